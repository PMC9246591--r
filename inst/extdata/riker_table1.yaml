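# Riker SAS grading counts of the two 30-patient anesthesia groups
# (grades 3-7; group A dexmedetomidine, group B saline control)
grades: [3, 4, 5, 6, 7]
counts:
  A: [5, 20, 3, 2, 0]
  B: [2, 5, 7, 9, 7]
threshold: 5
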