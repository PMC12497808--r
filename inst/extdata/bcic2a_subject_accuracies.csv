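method,subject,accuracy
EEGNet-8.2,A01,78.82
EEGNet-8.2,A02,56.26
EEGNet-8.2,A03,88.54
EEGNet-8.2,A04,69.44
EEGNet-8.2,A05,75.00
EEGNet-8.2,A06,60.76
EEGNet-8.2,A07,72.92
EEGNet-8.2,A08,76.04
EEGNet-8.2,A09,74.31
TSFCNet,A01,90.28
TSFCNet,A02,62.50
TSFCNet,A03,93.40
TSFCNet,A04,83.33
TSFCNet,A05,75.35
TSFCNet,A06,68.06
TSFCNet,A07,95.49
TSFCNet,A08,88.19
TSFCNet,A09,87.85
MSCFormer,A01,86.11
MSCFormer,A02,65.42
MSCFormer,A03,94.10
MSCFormer,A04,85.97
MSCFormer,A05,80.42
MSCFormer,A06,74.58
MSCFormer,A07,89.93
MSCFormer,A08,84.79
MSCFormer,A09,85.21
TCNet-Fusion,A01,90.74
TCNet-Fusion,A02,70.67
TCNet-Fusion,A03,95.23
TCNet-Fusion,A04,76.75
TCNet-Fusion,A05,82.24
TCNet-Fusion,A06,68.83
TCNet-Fusion,A07,94.22
TCNet-Fusion,A08,88.92
TCNet-Fusion,A09,85.98
EEG-TCNet,A01,85.77
EEG-TCNet,A02,65.02
EEG-TCNet,A03,94.51
EEG-TCNet,A04,64.91
EEG-TCNet,A05,75.36
EEG-TCNet,A06,61.40
EEG-TCNet,A07,87.36
EEG-TCNet,A08,83.76
EEG-TCNet,A09,78.03
Conformer,A01,88.19
Conformer,A02,61.46
Conformer,A03,93.40
Conformer,A04,78.13
Conformer,A05,52.08
Conformer,A06,65.28
Conformer,A07,92.36
Conformer,A08,88.19
Conformer,A09,88.89
Proposed,A01,88.19
Proposed,A02,75.35
Proposed,A03,95.49
Proposed,A04,84.72
Proposed,A05,77.78
Proposed,A06,71.53
Proposed,A07,95.14
Proposed,A08,89.24
Proposed,A09,86.81
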