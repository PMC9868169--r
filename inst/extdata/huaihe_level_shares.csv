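zone,year,I,II,III,IV,V,VI,VII,VIII
huaihe_basin,1990,0.59,11.11,13.98,45.59,27.43,1.18,0.10,0.01
huaihe_basin,1995,0.48,11.45,8.46,45.39,31.46,2.51,0.22,0.02
huaihe_basin,2000,0.42,9.74,8.44,43.70,34.19,3.23,0.23,0.05
huaihe_basin,2005,0.42,9.72,7.93,33.44,41.62,6.45,0.34,0.07
huaihe_basin,2010,0.57,10.27,7.33,32.92,45.47,2.89,0.47,0.07
huaihe_basin,2015,0.68,10.84,9.50,57.22,19.73,1.60,0.39,0.04
huaihe_basin,2018,0.50,10.60,14.59,64.57,8.28,0.93,0.45,0.06
upstream,1990,0.03,18.41,22.80,38.26,20.39,0.12,0.01,0.00
upstream,1995,0.02,20.28,9.31,44.97,24.85,0.50,0.07,0.00
upstream,2000,0.02,17.07,9.86,46.36,26.27,0.37,0.05,0.00
upstream,2005,0.04,16.79,7.66,40.71,33.14,1.54,0.11,0.01
upstream,2010,0.13,17.49,5.91,43.52,32.14,0.71,0.10,0.02
upstream,2015,0.13,17.03,12.24,58.50,11.43,0.54,0.12,0.02
upstream,2018,0.07,18.99,20.86,55.71,3.73,0.39,0.22,0.03
midstream,1990,0.85,11.17,9.58,34.70,42.12,1.50,0.07,0.01
midstream,1995,0.79,11.11,5.58,34.83,43.19,4.27,0.21,0.03
midstream,2000,0.59,10.43,4.77,32.33,45.64,5.92,0.23,0.07
midstream,2005,0.68,10.28,4.80,25.15,46.10,12.54,0.37,0.08
midstream,2010,0.81,10.63,4.63,25.48,53.83,4.19,0.36,0.06
midstream,2015,1.03,10.74,6.69,49.05,30.88,1.18,0.37,0.05
midstream,2018,0.95,10.73,9.97,65.16,12.05,0.70,0.36,0.08
downstream,1990,1.60,5.86,18.24,69.81,3.57,0.88,0.04,0.00
downstream,1995,1.17,6.96,6.98,76.60,7.30,0.83,0.16,0.00
downstream,2000,1.38,5.85,8.33,73.64,9.57,1.15,0.09,0.00
downstream,2005,1.28,5.62,7.49,60.55,23.38,1.58,0.10,0.00
downstream,2010,1.88,5.56,6.57,58.03,25.98,1.66,0.25,0.07
downstream,2015,1.95,6.12,11.80,74.82,3.77,1.27,0.23,0.04
downstream,2018,0.73,7.05,20.96,67.80,2.94,0.41,0.10,0.01
yishusihe,1990,0.10,6.63,11.53,49.91,30.61,1.06,0.14,0.02
yishusihe,1995,0.01,6.79,11.38,41.44,38.44,1.69,0.22,0.02
yishusihe,2000,0.10,4.98,11.03,41.10,40.70,1.77,0.26,0.05
yishusihe,2005,0.02,4.91,11.16,25.88,54.34,3.23,0.38,0.08
yishusihe,2010,0.18,5.96,10.75,26.40,54.02,2.05,0.56,0.09
yishusihe,2015,0.19,7.27,10.99,60.16,19.17,1.83,0.38,0.01
yishusihe,2018,0.10,6.49,12.61,71.21,7.96,1.21,0.37,0.05
shandong_peninsula,1990,0.43,15.17,19.72,55.26,7.83,1.39,0.18,0.01
shandong_peninsula,1995,0.33,15.60,11.29,57.66,13.03,1.73,0.33,0.04
shandong_peninsula,2000,0.17,12.40,12.27,54.72,18.16,1.90,0.34,0.05
shandong_peninsula,2005,0.15,12.91,10.69,43.40,29.67,2.64,0.47,0.07
shandong_peninsula,2010,0.14,13.52,9.75,39.08,33.56,2.95,0.88,0.11
shandong_peninsula,2015,0.18,14.62,11.08,61.31,9.16,2.91,0.68,0.04
shandong_peninsula,2018,0.18,12.58,20.70,57.92,5.86,1.63,1.07,0.05
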