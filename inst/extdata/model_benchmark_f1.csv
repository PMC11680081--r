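model,feature,weighted_f1
AlexNet,mel,0.81
AlexNet,mfcc,0.90
AlexNet,lfcc,0.81
DenseNet,mel,0.90
DenseNet,mfcc,0.86
DenseNet,lfcc,0.86
EfficientNet,mel,0.81
EfficientNet,mfcc,0.86
EfficientNet,lfcc,0.90
ResNet50,mel,0.86
ResNet50,mfcc,0.86
ResNet50,lfcc,0.86
ResNet152,mel,0.81
ResNet152,mfcc,0.86
ResNet152,lfcc,0.86
SVM,mel,0.81
SVM,mfcc,0.86
SVM,lfcc,0.85
KNN,mel,0.64
KNN,mfcc,0.76
KNN,lfcc,0.76
NaiveBayes,mel,0.86
NaiveBayes,mfcc,0.87
NaiveBayes,lfcc,0.87
RandomForest,mel,0.86
RandomForest,mfcc,0.87
RandomForest,lfcc,0.86
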