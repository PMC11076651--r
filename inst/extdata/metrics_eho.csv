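extraction,classifier,accuracy,precision,f1,mcc,fm,error_rate,jaccard,csi,gmean,kappa
EM,SVM_LINEAR,56.62,62.86,59.86,0.13,0.60,43.38,42.72,20.00,56.06,0.13
EM,SVM_POLY,61.77,67.61,64.87,0.23,0.65,38.24,48.00,29.94,61.19,0.23
EM,SVM_RBF,86.03,88.16,87.58,0.72,0.88,13.97,77.91,75.17,85.71,0.72
EM,RANDOM_FOREST,73.53,76.62,76.62,0.46,0.77,26.47,62.11,53.25,72.97,0.46
EM,DECISION_TREE,74.27,76.25,77.71,0.47,0.78,25.74,63.54,55.47,73.80,0.47
EM,QDA,83.82,87.67,85.33,0.67,0.85,16.18,74.42,70.79,83.42,0.67
EM,ADABOOST,85.29,89.04,86.67,0.70,0.87,14.71,76.47,73.46,84.90,0.70
EM,XGBOOST,88.24,90.67,89.47,0.76,0.90,11.77,80.95,78.98,87.92,0.76
NLR,SVM_LINEAR,57.35,63.77,60.27,0.15,0.60,42.65,43.14,20.91,56.89,0.15
NLR,SVM_POLY,72.79,79.41,74.48,0.46,0.75,27.21,59.34,49.54,72.49,0.46
NLR,SVM_RBF,86.77,87.34,88.46,0.73,0.89,13.24,79.31,76.95,86.65,0.73
NLR,RANDOM_FOREST,83.09,86.49,84.77,0.66,0.85,16.91,73.56,69.60,82.68,0.66
NLR,DECISION_TREE,84.56,86.84,86.28,0.69,0.86,15.44,75.86,72.56,84.22,0.69
NLR,QDA,77.21,77.38,80.75,0.53,0.81,22.79,67.71,61.80,77.15,0.53
NLR,ADABOOST,75.00,76.54,78.48,0.49,0.79,25.00,64.58,57.06,74.61,0.49
NLR,XGBOOST,88.24,90.67,89.47,0.76,0.90,11.77,80.95,78.98,87.92,0.76
KMEANS,SVM_LINEAR,63.97,70.59,66.21,0.28,0.66,36.03,49.49,32.93,63.63,0.28
KMEANS,SVM_POLY,58.09,64.29,61.22,0.16,0.61,41.91,44.12,22.73,57.55,0.16
KMEANS,SVM_RBF,90.44,93.24,91.39,0.81,0.91,9.56,84.15,82.85,90.12,0.81
KMEANS,RANDOM_FOREST,75.00,81.16,76.71,0.50,0.77,25.00,62.22,53.89,74.65,0.50
KMEANS,DECISION_TREE,75.00,76.54,78.48,0.49,0.79,25.00,64.58,57.06,74.61,0.49
KMEANS,QDA,75.00,75.29,79.01,0.49,0.79,25.00,65.31,58.41,74.90,0.48
KMEANS,ADABOOST,72.79,76.32,75.82,0.45,0.76,27.21,61.05,51.64,72.21,0.45
KMEANS,XGBOOST,81.62,83.33,83.87,0.63,0.84,18.38,72.22,67.75,81.30,0.63
PCA,SVM_LINEAR,72.06,78.26,73.97,0.44,0.74,27.94,58.70,48.39,71.69,0.44
PCA,SVM_POLY,63.97,68.92,67.55,0.27,0.68,36.03,51.00,35.15,63.26,0.27
PCA,SVM_RBF,91.18,93.33,92.11,0.82,0.92,8.82,85.37,84.24,90.90,0.82
PCA,RANDOM_FOREST,84.56,87.84,86.09,0.69,0.86,15.44,75.58,72.25,84.17,0.69
PCA,DECISION_TREE,84.56,87.84,86.09,0.69,0.86,15.44,75.58,72.25,84.17,0.69
PCA,QDA,88.24,90.67,89.47,0.76,0.90,11.77,80.95,78.98,87.92,0.76
PCA,ADABOOST,89.71,92.00,90.79,0.79,0.91,10.29,83.13,81.61,89.41,0.79
PCA,XGBOOST,91.18,93.33,92.11,0.82,0.92,8.82,85.37,84.24,90.90,0.82
DCT,SVM_LINEAR,63.24,68.49,66.67,0.26,0.67,36.77,50.00,33.43,62.56,0.26
DCT,SVM_POLY,72.06,80.00,73.24,0.45,0.74,27.94,57.78,47.53,71.99,0.44
DCT,SVM_RBF,94.85,97.30,95.36,0.90,0.95,5.15,91.14,90.80,94.58,0.90
DCT,RANDOM_FOREST,80.88,84.00,82.90,0.61,0.83,19.12,70.79,65.82,80.45,0.61
DCT,DECISION_TREE,88.24,91.78,89.33,0.76,0.89,11.77,80.72,78.79,87.87,0.76
DCT,QDA,90.44,93.24,91.39,0.81,0.91,9.56,84.15,82.85,90.12,0.81
DCT,ADABOOST,91.91,94.60,92.72,0.84,0.93,8.09,86.42,85.50,91.61,0.84
DCT,XGBOOST,94.12,98.59,94.60,0.89,0.95,5.88,89.74,89.50,93.79,0.88
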