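algorithm,mixed_completed,mixed_failed,discrete_completed,discrete_failed,continuous_completed,continuous_failed,total_failed
LR,93,9,29,5,138,19,33
C45,101,1,34,0,157,0,1
SVM,101,1,33,1,157,0,2
AB,96,6,32,2,153,4,12
kNN,101,1,33,1,157,0,2
NB,102,0,34,0,157,0,0
RF,95,7,33,1,152,5,13
BP,68,34,25,9,133,24,67
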