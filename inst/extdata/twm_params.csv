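w2,A,B,C,a,b,lambda,h
0,-374.974,14025.4,55.2935,-2.84474,-2999.98,1.8e-5,1.17563e8
0.1,-210.273,7229.53,30.6005,-4.32968,-2192.64,2.1e-5,5.53818e7
0.2,1291.7,-62115.9,-192.138,-1.40214,-2954.84,1.35e-4,1.72846e7
0.3,845.029,-42649.8,-125.119,2.97107,-4124.51,7.02e-4,4.81956e6
0.4,-3387.62,150906,503.981,4.20757,-4273.88,2.208e-3,1.67214e6
0.5,1816.02,-86808.6,-269.254,3.92576,-3902.93,4.872e-3,6.93367e5
0.6,339.704,-17966,-50.5433,-0.456256,-2403.26,1.494e-3,1.00325e6
0.7,57.707,-4651.25,-8.79499,-1.483921,-1943.19,1.193e-3,7.06422e5
0.8,-615.06,25244.2,91.7279,-2.27488,-3019.63,9.504e-3,2.23656e5
0.9,-1264.99,55224.9,188.166,1.38631,-2713.24,1.0772e-2,1.69065e5
1,456.071,-23804.5,-67.4966,1.81408,-3021.68,1.5432e-2,1.45412e5
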