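#eef synthetic illustrative stand-in for pol-gamma base-incorporation kinetics
#eef constructed values, NOT experimental measurements; reproduces only the
#eef qualitative (k_bar, Q) layout of the named system among polymerase systems
#eef units: arbitrary reference rate units (apparent second-order constants)
#eef alphabet: dna
	A	T	G	C
A	  0.00785	      883	  0.00838	  0.00905
T	      394	  0.00345	   0.0136	   0.0158
G	   0.0137	  0.00927	  0.00452	      515
C	   0.0122	   0.0138	      481	   0.0057
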