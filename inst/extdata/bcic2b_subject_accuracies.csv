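method,subject,accuracy
EEGNet,B01,71.88
EEGNet,B02,70.71
EEGNet,B03,88.75
EEGNet,B04,96.56
EEGNet,B05,94.69
EEGNet,B06,76.56
EEGNet,B07,89.06
EEGNet,B08,95.00
EEGNet,B09,78.44
TSFCNet,B01,76.25
TSFCNet,B02,70.00
TSFCNet,B03,83.75
TSFCNet,B04,97.50
TSFCNet,B05,92.81
TSFCNet,B06,86.56
TSFCNet,B07,88.44
TSFCNet,B08,92.50
TSFCNet,B09,89.69
MSCFormer,B01,78.06
MSCFormer,B02,71.21
MSCFormer,B03,82.75
MSCFormer,B04,97.69
MSCFormer,B05,96.81
MSCFormer,B06,87.81
MSCFormer,B07,94.00
MSCFormer,B08,94.75
MSCFormer,B09,88.88
Conformer,B01,82.50
Conformer,B02,65.71
Conformer,B03,63.75
Conformer,B04,98.44
Conformer,B05,86.56
Conformer,B06,90.31
Conformer,B07,87.81
Conformer,B08,94.38
Conformer,B09,92.19
Proposed,B01,81.25
Proposed,B02,73.21
Proposed,B03,87.81
Proposed,B04,98.12
Proposed,B05,97.19
Proposed,B06,85.00
Proposed,B07,95.00
Proposed,B08,95.00
Proposed,B09,83.13
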