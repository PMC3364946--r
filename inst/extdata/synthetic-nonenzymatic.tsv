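#eef synthetic illustrative stand-in for nonenzymatic base-incorporation kinetics
#eef constructed values, NOT experimental measurements; reproduces only the
#eef qualitative (k_bar, Q) layout of the named system among polymerase systems
#eef units: arbitrary reference rate units (apparent second-order constants)
#eef alphabet: dna
	A	T	G	C
A	 0.000384	   0.0128	  0.00083	 0.000956
T	   0.0172	 0.000616	  0.00114	 0.000368
G	 0.000656	  0.00105	 0.000533	   0.0222
C	 0.000439	 0.000797	   0.0233	 0.000274
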