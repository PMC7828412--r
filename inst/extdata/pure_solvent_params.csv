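solvent_id,A,B,C,a,b,lambda,h
water,-374.54,14006.70,55.25,-2.72,-2997.05,3.0e-5,8.15e7
methanol,490.45,-26827.80,-72.07,5.46,-4646.29,2.94e-3,1.55296e6
ethanol,787.98,-41435.30,-115.39,11.44,-5922.71,5.973e-2,9.960e4
1-propanol,273.94,-14746.60,-40.67,0.25,-2229.99,2.98e-3,5.8115e5
2-propanol,205.50,-13595.70,-29.52,6.88,-4512.17,1.643e-2,2.6880e5
1-butanol,-65.44,1399.93,9.42,-2.07,-1497.91,6.1e-4,9.5468e5
2-butanol,841.86,-43078.50,-123.77,8.97,-4988.55,4.456e-2,1.1099e5
acetonitrile,120.15,-7033.34,-18.25,-2.66,-1417.25,4.0e-4,1.349e6
acetone,-318.55,12641.10,47.25,-0.58,-1900.52,2.25e-3,5.7021e5
ethyl_acetate,-31.99,264.30,4.17,-3.93,-1018.83,1.9e-4,1.93612e6
thp,456.50,-23707.90,-67.25,3.92,-3010.37,2.587e-2,1.0647e5
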