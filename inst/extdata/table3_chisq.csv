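algorithm,chi2,different
LR,3.8052,no
C45,2.9952,no
SVM,2.1799,no
AB,4.2213,no
kNN,3.8980,no
NB,11.2935,yes
RF,7.9518,no
BP,7.5466,no
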