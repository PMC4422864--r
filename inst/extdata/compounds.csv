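name,formula
glutamate,C5H9NO4
"fructose 1,6-bisphosphate",C6H14O12P2
AMP,C10H14N5O7P
ADP,C10H15N5O10P2
ATP,C10H16N5O13P3
lactate,C3H6O3
pyruvate,C3H4O3
glucose,C6H12O6
creatine,C4H9N3O2
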