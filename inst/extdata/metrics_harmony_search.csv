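extraction,classifier,accuracy,precision,f1,mcc,fm,error_rate,jaccard,csi,gmean,kappa
EM,SVM_LINEAR,63.24,68.00,67.11,0.26,0.67,36.77,50.50,34.23,62.46,0.26
EM,SVM_POLY,70.59,77.61,72.22,0.42,0.72,29.41,56.52,45.14,70.35,0.41
EM,SVM_RBF,84.56,90.00,85.71,0.69,0.86,15.44,75.00,71.82,84.21,0.69
EM,RANDOM_FOREST,82.35,85.33,84.21,0.64,0.84,17.65,72.73,68.45,81.94,0.64
EM,DECISION_TREE,72.79,76.32,75.82,0.45,0.76,27.21,61.05,51.64,72.21,0.45
EM,QDA,84.56,87.84,86.09,0.69,0.86,15.44,75.58,72.25,84.17,0.69
EM,ADABOOST,79.41,83.56,81.33,0.59,0.81,20.59,68.54,62.78,78.96,0.58
EM,XGBOOST,81.62,86.11,83.22,0.63,0.83,18.38,71.26,66.63,81.20,0.63
NLR,SVM_LINEAR,58.09,64.71,60.69,0.16,0.61,41.91,43.56,21.85,57.71,0.16
NLR,SVM_POLY,58.82,64.79,62.16,0.17,0.62,41.18,45.10,24.53,58.22,0.17
NLR,SVM_RBF,83.82,85.71,85.71,0.67,0.86,16.18,75.00,71.43,83.51,0.67
NLR,RANDOM_FOREST,72.79,83.33,72.99,0.48,0.74,27.21,57.47,48.27,73.30,0.46
NLR,DECISION_TREE,73.53,81.54,74.65,0.48,0.75,26.47,59.55,50.37,73.47,0.47
NLR,QDA,86.77,89.33,88.16,0.73,0.88,13.24,78.82,76.35,86.42,0.73
NLR,ADABOOST,80.15,83.78,82.12,0.60,0.82,19.85,69.66,64.30,79.70,0.60
NLR,XGBOOST,83.82,86.67,85.53,0.67,0.86,16.18,74.71,71.08,83.44,0.67
KMEANS,SVM_LINEAR,54.41,60.87,57.53,0.09,0.58,45.59,40.39,15.42,53.92,0.09
KMEANS,SVM_POLY,58.82,64.79,62.16,0.17,0.62,41.18,45.10,24.53,58.22,0.17
KMEANS,SVM_RBF,72.06,85.46,71.21,0.48,0.72,27.94,55.29,46.49,73.35,0.46
KMEANS,RANDOM_FOREST,71.32,81.67,71.53,0.45,0.72,28.68,55.68,45.30,71.82,0.44
KMEANS,DECISION_TREE,67.65,73.24,70.27,0.35,0.70,32.35,54.17,40.77,67.14,0.35
KMEANS,QDA,72.06,76.71,74.67,0.44,0.75,27.94,59.57,49.44,71.51,0.44
KMEANS,ADABOOST,80.88,85.92,82.43,0.62,0.83,19.12,70.12,65.14,80.48,0.62
KMEANS,XGBOOST,84.56,87.84,86.09,0.69,0.86,15.44,75.58,72.25,84.17,0.69
PCA,SVM_LINEAR,55.88,62.32,58.90,0.12,0.59,44.12,41.75,18.16,55.40,0.12
PCA,SVM_POLY,57.35,63.77,60.27,0.15,0.60,42.65,43.14,20.91,56.89,0.15
PCA,SVM_RBF,74.27,85.00,74.45,0.51,0.75,25.74,59.30,51.23,74.78,0.49
PCA,RANDOM_FOREST,79.41,83.56,81.33,0.59,0.81,20.59,68.54,62.78,78.96,0.58
PCA,DECISION_TREE,73.53,82.54,74.29,0.49,0.75,26.47,59.09,50.07,73.67,0.48
PCA,QDA,75.00,76.54,78.48,0.49,0.79,25.00,64.58,57.06,74.61,0.49
PCA,ADABOOST,76.47,77.78,79.75,0.52,0.80,23.53,66.32,59.60,76.14,0.52
PCA,XGBOOST,72.79,78.57,74.83,0.46,0.75,27.21,59.78,50.00,72.38,0.45
DCT,SVM_LINEAR,55.88,61.97,59.46,0.11,0.60,44.12,42.31,19.12,55.24,0.11
DCT,SVM_POLY,58.09,63.51,62.25,0.15,0.62,41.91,45.19,24.55,57.26,0.15
DCT,SVM_RBF,80.88,84.00,82.90,0.61,0.83,19.12,70.79,65.82,80.45,0.61
DCT,RANDOM_FOREST,73.53,78.87,75.68,0.47,0.76,26.47,60.87,51.60,73.07,0.47
DCT,DECISION_TREE,78.68,82.43,80.80,0.57,0.81,21.32,67.78,61.65,78.21,0.57
DCT,QDA,84.56,86.84,86.28,0.69,0.86,15.44,75.86,72.56,84.22,0.69
DCT,ADABOOST,74.27,75.00,78.26,0.47,0.78,25.74,64.29,56.82,74.03,0.47
DCT,XGBOOST,77.21,79.49,80.00,0.54,0.80,22.79,66.67,60.01,76.77,0.54
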