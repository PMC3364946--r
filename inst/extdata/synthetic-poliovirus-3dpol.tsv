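#eef synthetic illustrative stand-in for poliovirus-3dpol base-incorporation kinetics
#eef constructed values, NOT experimental measurements; reproduces only the
#eef qualitative (k_bar, Q) layout of the named system among polymerase systems
#eef units: arbitrary reference rate units (apparent second-order constants)
#eef alphabet: dna
	A	T	G	C
A	   0.0118	      144	   0.0348	   0.0121
T	      165	   0.0161	   0.0364	   0.0154
G	   0.0195	   0.0201	     0.04	      214
C	   0.0133	   0.0154	      218	   0.0166
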