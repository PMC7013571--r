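method,accuracy,cv10,precision,sensitivity,f1,auc,specificity
SVM (linear),0.93,0.92,0.95,0.94,0.94,0.98,0.94
Logistic Regression,0.89,0.89,0.82,0.88,0.85,0.95,0.88
Naive Bayes,0.88,0.84,0.89,0.92,0.90,0.93,0.92
KNN,0.60,0.58,0.66,0.73,0.69,0.55,0.73
Random Forest,0.91,0.90,0.94,0.91,0.92,0.97,0.91
BP Neural Network,0.92,0.90,0.95,0.93,0.94,0.97,0.93
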