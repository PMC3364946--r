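#eef synthetic illustrative stand-in for dpo4 base-incorporation kinetics
#eef constructed values, NOT experimental measurements; reproduces only the
#eef qualitative (k_bar, Q) layout of the named system among polymerase systems
#eef units: arbitrary reference rate units (apparent second-order constants)
#eef alphabet: dna
	A	T	G	C
A	    0.176	     48.1	    0.115	    0.171
T	     33.3	   0.0995	   0.0578	   0.0551
G	   0.0985	    0.147	    0.237	     57.6
C	     0.08	    0.107	     46.5	    0.143
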