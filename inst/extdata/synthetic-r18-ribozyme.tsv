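#eef synthetic illustrative stand-in for r18-ribozyme base-incorporation kinetics
#eef constructed values, NOT experimental measurements; reproduces only the
#eef qualitative (k_bar, Q) layout of the named system among polymerase systems
#eef units: arbitrary reference rate units (apparent second-order constants)
#eef alphabet: dna
	A	T	G	C
A	  0.00485	     1.06	   0.0155	   0.0131
T	     1.14	  0.00823	  0.00847	  0.00755
G	   0.0201	   0.0174	    0.011	     1.11
C	  0.00715	   0.0122	     1.38	   0.0163
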