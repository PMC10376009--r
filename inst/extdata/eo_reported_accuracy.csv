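backbone,accuracy_pct,sd_pct
DarkNet-19,89.7,2.7
DarkNet-53,92.1,1.7
DenseNet-201,90.8,1.9
EfficientNet-b0,91.7,2.4
GoogLeNet365,89.6,2.3
GoogLeNet,89.0,2.6
Inception-ResNet-v2,94.2,2.3
Inception-v3,91.5,2.9
MobileNet-v2,92.2,1.5
NASNet-Mobile,91.2,2.2
ResNet-101,93.4,2.0
ResNet-50,94.7,2.5
ResNet-18,87.5,2.1
ShuffleNet,89.4,1.7
SqueezeNet,90.0,2.1
Xception,92.4,2.3
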