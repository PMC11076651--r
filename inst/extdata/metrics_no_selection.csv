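extraction,classifier,accuracy,precision,f1,mcc,fm,error_rate,jaccard,csi,gmean,kappa
EM,SVM_LINEAR,55.88,62.32,58.90,0.12,0.59,44.12,41.75,18.16,55.40,0.12
EM,SVM_POLY,57.35,63.77,60.27,0.15,0.60,42.65,43.14,20.91,56.89,0.15
EM,SVM_RBF,69.12,80.70,68.66,0.41,0.69,30.88,52.27,40.44,70.02,0.40
EM,RANDOM_FOREST,62.50,68.57,65.31,0.25,0.65,37.50,48.48,30.91,62.00,0.25
EM,DECISION_TREE,62.50,67.11,66.67,0.24,0.67,37.50,50.00,33.34,61.67,0.24
EM,QDA,65.44,72.06,67.59,0.31,0.68,34.56,51.04,35.70,65.11,0.31
EM,ADABOOST,69.12,73.97,72.00,0.38,0.72,30.88,56.25,44.10,68.53,0.38
EM,XGBOOST,72.79,77.78,75.17,0.45,0.75,27.21,60.22,50.51,72.29,0.45
NLR,SVM_LINEAR,58.09,66.67,58.39,0.18,0.59,41.91,41.24,18.61,58.49,0.17
NLR,SVM_POLY,68.38,72.37,71.90,0.36,0.72,31.62,56.12,43.80,67.70,0.36
NLR,SVM_RBF,75.74,82.35,77.24,0.52,0.77,24.26,62.92,55.08,75.45,0.51
NLR,RANDOM_FOREST,72.06,83.05,72.06,0.47,0.73,27.94,56.32,46.69,72.70,0.45
NLR,DECISION_TREE,73.53,83.61,73.91,0.49,0.74,26.47,58.62,49.84,73.91,0.48
NLR,QDA,73.53,80.60,75.00,0.48,0.75,26.47,60.00,50.73,73.30,0.47
NLR,ADABOOST,74.26,76.92,77.42,0.48,0.77,25.74,63.16,54.85,73.74,0.48
NLR,XGBOOST,78.68,82.43,80.79,0.57,0.81,21.32,67.78,61.65,78.20,0.57
KMEANS,SVM_LINEAR,59.56,66.67,61.54,0.20,0.62,40.44,44.44,23.81,59.36,0.19
KMEANS,SVM_POLY,59.56,65.71,62.59,0.19,0.63,40.44,45.54,25.45,59.03,0.19
KMEANS,SVM_RBF,76.47,84.62,77.46,0.54,0.78,23.53,63.22,56.04,76.42,0.53
KMEANS,RANDOM_FOREST,72.79,82.26,73.38,0.47,0.74,27.21,57.95,48.49,73.05,0.46
KMEANS,DECISION_TREE,57.35,63.77,60.27,0.15,0.60,42.65,43.14,20.91,56.89,0.15
KMEANS,QDA,72.06,76.71,74.67,0.44,0.75,27.94,59.57,49.44,71.51,0.44
KMEANS,ADABOOST,72.79,76.32,75.82,0.45,0.76,27.21,61.05,51.64,72.21,0.45
KMEANS,XGBOOST,83.82,87.67,85.33,0.67,0.85,16.18,74.42,70.79,83.41,0.67
PCA,SVM_LINEAR,58.82,65.67,61.11,0.18,0.61,41.18,44.00,22.81,58.54,0.18
PCA,SVM_POLY,57.35,63.77,60.27,0.15,0.60,42.65,43.14,20.91,56.89,0.15
PCA,SVM_RBF,72.06,85.45,71.21,0.48,0.72,27.94,55.29,46.49,73.35,0.45
PCA,RANDOM_FOREST,66.91,72.86,69.39,0.34,0.69,33.09,53.13,39.09,66.45,0.34
PCA,DECISION_TREE,66.91,72.22,69.80,0.33,0.70,33.09,53.61,39.75,66.34,0.33
PCA,QDA,72.79,80.30,74.13,0.46,0.74,27.21,58.89,49.13,72.64,0.46
PCA,ADABOOST,68.38,75.00,70.34,0.37,0.70,31.62,54.26,41.23,68.06,0.37
PCA,XGBOOST,71.32,76.39,73.83,0.42,0.74,28.68,58.51,47.82,70.80,0.42
DCT,SVM_LINEAR,59.56,66.18,62.07,0.19,0.62,40.44,45.00,24.62,59.19,0.19
DCT,SVM_POLY,62.50,68.57,65.31,0.25,0.65,37.50,48.48,30.91,62.00,0.25
DCT,SVM_RBF,79.41,86.57,80.56,0.60,0.81,20.59,67.44,61.89,79.20,0.59
DCT,RANDOM_FOREST,75.00,75.90,78.75,0.49,0.79,25.00,64.95,57.72,74.74,0.48
DCT,DECISION_TREE,83.09,86.49,84.77,0.66,0.85,16.91,73.56,69.60,82.68,0.66
DCT,QDA,64.71,70.42,67.57,0.29,0.68,35.29,51.02,35.36,64.16,0.29
DCT,ADABOOST,72.79,78.57,74.83,0.46,0.75,27.21,59.78,50.00,72.37,0.45
DCT,XGBOOST,86.03,90.28,87.25,0.72,0.87,13.97,77.38,74.69,85.65,0.72
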