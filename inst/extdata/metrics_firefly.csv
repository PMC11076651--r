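extraction,classifier,accuracy,precision,f1,mcc,fm,error_rate,jaccard,csi,gmean,kappa
EM,SVM_LINEAR,60.29,67.16,62.50,0.21,0.63,39.71,45.46,25.61,60.01,0.21
EM,SVM_POLY,72.79,85.71,72.18,0.49,0.73,27.21,56.47,48.05,73.92,0.47
EM,SVM_RBF,72.79,84.48,72.59,0.49,0.73,27.21,56.98,48.12,73.59,0.47
EM,RANDOM_FOREST,72.79,83.33,72.99,0.48,0.74,27.21,57.47,48.27,73.30,0.46
EM,DECISION_TREE,72.79,78.57,74.83,0.46,0.75,27.21,59.78,50.00,72.38,0.45
EM,QDA,75.00,75.90,78.75,0.49,0.79,25.00,64.95,57.72,74.74,0.49
EM,ADABOOST,86.03,89.19,87.42,0.72,0.87,13.97,77.65,74.90,85.65,0.72
EM,XGBOOST,86.03,90.28,87.25,0.72,0.87,13.97,77.38,74.69,85.65,0.72
NLR,SVM_LINEAR,66.91,73.53,68.97,0.34,0.69,33.09,52.63,38.46,66.58,0.34
NLR,SVM_POLY,73.53,82.54,74.29,0.49,0.75,26.47,59.09,50.07,73.67,0.48
NLR,SVM_RBF,78.68,88.71,79.14,0.59,0.80,21.32,65.48,60.14,78.95,0.58
NLR,RANDOM_FOREST,72.79,76.32,75.82,0.45,0.76,27.21,61.05,51.64,72.21,0.45
NLR,DECISION_TREE,78.68,83.33,80.54,0.57,0.81,21.32,67.42,61.26,78.23,0.57
NLR,QDA,82.35,86.30,84.00,0.65,0.84,17.65,72.41,68.12,81.93,0.64
NLR,ADABOOST,85.29,89.04,86.67,0.70,0.87,14.71,76.47,73.46,84.90,0.70
NLR,XGBOOST,88.97,89.74,90.32,0.78,0.90,11.03,82.35,80.65,88.83,0.78
KMEANS,SVM_LINEAR,56.62,62.86,59.86,0.13,0.60,43.38,42.72,20.00,56.06,0.13
KMEANS,SVM_POLY,57.35,63.77,60.27,0.15,0.60,42.65,43.14,20.91,56.89,0.15
KMEANS,SVM_RBF,73.53,88.68,72.31,0.52,0.74,26.47,56.63,49.72,75.25,0.49
KMEANS,RANDOM_FOREST,83.82,85.71,85.71,0.67,0.86,16.18,75.00,71.43,83.51,0.67
KMEANS,DECISION_TREE,73.53,76.62,76.62,0.46,0.77,26.47,62.11,53.25,72.97,0.46
KMEANS,QDA,75.74,76.83,79.25,0.50,0.79,24.27,65.63,58.65,75.44,0.50
KMEANS,ADABOOST,83.82,87.67,85.33,0.67,0.85,16.18,74.42,70.79,83.42,0.67
KMEANS,XGBOOST,86.03,88.16,87.58,0.72,0.88,13.97,77.91,75.17,85.71,0.72
PCA,SVM_LINEAR,57.35,64.62,59.16,0.15,0.59,42.65,42.00,19.16,57.24,0.15
PCA,SVM_POLY,58.82,66.67,60.00,0.19,0.60,41.18,42.86,21.21,58.91,0.18
PCA,SVM_RBF,85.29,92.54,86.11,0.71,0.86,14.71,75.61,73.06,85.10,0.71
PCA,RANDOM_FOREST,60.29,67.69,61.97,0.21,0.62,39.71,44.90,24.84,60.19,0.21
PCA,DECISION_TREE,72.06,85.46,71.21,0.48,0.72,27.94,55.29,46.49,73.35,0.46
PCA,QDA,73.53,82.54,74.29,0.49,0.75,26.47,59.09,50.07,73.67,0.48
PCA,ADABOOST,73.53,83.61,73.91,0.49,0.74,26.47,58.62,49.84,73.91,0.48
PCA,XGBOOST,81.62,80.95,84.47,0.62,0.85,18.38,73.12,69.26,81.82,0.62
DCT,SVM_LINEAR,72.79,80.30,74.13,0.46,0.74,27.21,58.89,49.13,72.64,0.46
DCT,SVM_POLY,72.06,77.47,74.32,0.44,0.74,27.94,59.14,48.89,71.59,0.44
DCT,SVM_RBF,74.27,78.38,76.82,0.48,0.77,25.74,62.37,53.70,73.73,0.48
DCT,RANDOM_FOREST,75.00,76.54,78.48,0.49,0.79,25.00,64.58,57.06,74.61,0.49
DCT,DECISION_TREE,75.00,75.90,78.75,0.49,0.79,25.00,64.95,57.72,74.74,0.49
DCT,QDA,83.82,86.67,85.53,0.67,0.86,16.18,74.71,71.08,83.44,0.67
DCT,ADABOOST,85.29,88.00,86.84,0.70,0.87,14.71,76.74,73.71,84.93,0.70
DCT,XGBOOST,86.03,89.19,87.42,0.72,0.87,13.97,77.65,74.90,85.65,0.72
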