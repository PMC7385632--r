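zone,total_km2,optimum_km2,optimum_pct,suitable_km2,suitable_pct,secondary_km2,secondary_pct
Bayannur League,65135.08,3373.23,5.18,5026.24,7.72,27910.95,42.85
Baotou City,27889.94,5474.67,20.35,6995.39,25.08,14839.72,53.21
Wulanchabu City,54280.41,19572.31,36.06,17865.11,32.91,15525.56,28.60
Chifeng City,87353.27,15930.28,18.24,40437.60,46.29,29242.13,33.48
Tongliao City,58947.05,6931.52,11.74,22043.90,37.40,22822.72,38.72
Ordos City,87061.67,8083.03,9.20,30299.56,34.80,42744.99,49.10
Huhhot City,17031.10,7362.79,43.23,3786.03,22.23,3951.39,23.20
Xing'an League,54706.07,6068.60,11.09,22533.05,41.19,21293.88,38.92
Xilin Gol,199526.19,11969.12,6.00,32131.30,16.10,117752.88,59.02
Hulunbeir City,253561.97,3061.58,1.21,15869.45,6.26,89498.01,35.30
Wuhai City,1532.02,9.99,0.65,242.93,15.86,1243.70,81.18
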