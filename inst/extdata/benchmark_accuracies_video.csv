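participant,svm_microstate,svm_de,svm_psd,cnn_microstate,cnn_de,cnn_psd
CL,93.44,88.76,85.07,98.83,92.96,94.37
CSY,84.22,81.65,60.65,88.68,83.31,72.50
HH,82.15,83.78,78.96,77.18,86.57,83.80
LHY,87.25,82.69,81.34,53.85,88.69,83.80
LWX,89.90,80.05,88.81,99.39,88.45,86.62
RJ,89.65,93.08,81.34,63.94,81.925,83.10
SX,88.33,83.48,91.79,98.26,82.96,92.25
WCQ,92.36,84.86,81.25,92.47,84.32,87.04
WJQ,62.53,73.49,60.30,97.18,84.37,88.73
XD,85.08,86.47,84.78,91.94,59.58,38.06
XJ,83.43,76.71,63.48,87.59,85.185,63.889
XMX,89.82,85.86,86.49,97.922,83.59,62.47
YXK,75.60,86.23,65.94,76.48,86.71,94.37
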