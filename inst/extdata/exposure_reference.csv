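group,measured_laeq,measured_dose,predicted_laeq,predicted_dose
1,88.4,4.4,89.2,4.2
2,85.9,2.4,85.1,2.5
3,88.5,4.4,92.0,4.6
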