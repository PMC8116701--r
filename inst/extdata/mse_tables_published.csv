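size,times,mse_ex1,mse_ex2,mse_ex3
1,30,2.37144,2.83923,2.87982
1,60,1.48213,2.49541,2.71283
1,90,1.08587,2.06094,2.33112
1,120,1.04398,1.55052,2.03204
1,150,1.15137,1.21796,1.58001
1,180,1.27023,1.05704,1.27007
2,30_60,1.59044,2.94597,3.38164
2,30_90,1.04184,2.02553,2.47435
2,30_120,0.8313,1.52744,1.88487
2,30_150,0.77656,1.24404,1.54674
2,30_180,0.76386,1.04572,1.29145
2,60_90,1.01744,2.11078,2.63993
2,60_120,0.8628,1.53112,1.91978
2,60_150,0.84146,1.18311,1.49829
2,60_180,0.83782,1.00331,1.21676
2,90_120,0.90116,1.65281,2.14052
2,90_150,0.89505,1.23837,1.6483
2,90_180,0.91048,1.00323,1.29749
2,120_150,0.99535,1.22089,1.67092
2,120_180,1.00764,0.9865,1.34951
2,150_180,1.17352,0.97719,1.24635
3,30_60_90,1.01127,2.00212,2.43594
3,30_60_120,0.79361,1.49464,1.81317
3,30_60_150,0.72799,1.20321,1.48077
3,30_60_180,0.68501,0.98346,1.22154
3,30_90_120,0.75675,1.43671,1.80194
3,30_90_150,0.69878,1.17373,1.45919
3,30_90_180,0.67861,0.97652,1.2322
3,30_120_150,0.68581,1.09122,1.38739
3,30_120_180,0.67313,0.93237,1.18603
3,30_150_180,0.67858,0.8623,1.10814
3,60_90_120,0.79057,1.47998,1.86321
3,60_90_150,0.75929,1.1665,1.50283
3,60_90_180,0.75331,0.96534,1.23779
3,60_120_150,0.76469,1.07649,1.396
3,60_120_180,0.75608,0.9122,1.16991
3,60_150_180,0.77419,0.84264,1.08415
3,90_120_150,0.82071,1.14447,1.55208
3,90_120_180,0.81691,0.94613,1.2775
3,90_150_180,0.86003,0.88547,1.18735
3,120_150_180,0.95395,0.884564,1.23236
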