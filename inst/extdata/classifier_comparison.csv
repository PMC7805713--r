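id,cnn_accuracy,cnn_f1,svc_accuracy,svc_f1,rf_accuracy,rf_f1,dt_accuracy,dt_f1,knn_accuracy,knn_f1
1,0.79,0.77,0.77,0.72,0.80,0.78,0.77,0.75,0.81,0.79
2,0.64,0.62,0.58,0.55,0.75,0.75,0.65,0.64,0.72,0.71
3,0.65,0.59,0.66,0.55,0.67,0.61,0.65,0.58,0.67,0.61
4,0.82,0.79,0.82,0.76,0.83,0.81,0.82,0.79,0.83,0.81
5,0.92,0.91,0.89,0.87,0.93,0.92,0.90,0.89,0.93,0.93
6,0.91,0.89,0.92,0.90,0.90,0.89,0.91,0.89,0.92,0.90
7,0.73,0.73,0.61,0.59,0.80,0.80,0.72,0.71,0.80,0.80
8,0.75,0.74,0.51,0.47,0.82,0.82,0.66,0.66,0.82,0.81
9,0.64,0.57,0.63,0.56,0.65,0.60,0.63,0.57,0.67,0.61
10,0.87,0.87,0.79,0.77,0.88,0.87,0.82,0.82,0.85,0.85
11,0.77,0.76,0.69,0.65,0.78,0.77,0.72,0.71,0.76,0.74
12,0.83,0.78,0.81,0.74,0.84,0.81,0.82,0.79,0.84,0.80
13,0.77,0.77,0.73,0.69,0.79,0.80,0.77,0.77,0.79,0.80
14,0.79,0.79,0.70,0.69,0.82,0.81,0.73,0.73,0.81,0.81
15,0.91,0.90,0.87,0.83,0.92,0.90,0.90,0.88,0.92,0.91
16,0.64,0.62,0.61,0.57,0.67,0.65,0.62,0.60,0.68,0.66
17,0.84,0.84,0.70,0.69,0.88,0.88,0.76,0.75,0.84,0.84
18,0.78,0.78,0.63,0.60,0.79,0.78,0.61,0.58,0.78,0.78
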