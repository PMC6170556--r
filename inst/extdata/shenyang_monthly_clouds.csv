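month,indicator,ex,en,he,level
2016-11,PM2.5,73.5,39.93,23.36,2
2016-12,PM2.5,95.65,53.36,10.47,3
2017-01,PM2.5,88.84,56.46,9.74,3
2017-02,PM2.5,66.18,37.95,6.1,2
2017-03,PM2.5,83.03,45.81,16.47,3
2017-04,PM2.5,47.87,24.53,8.89,2
2017-05,PM2.5,40.94,15.04,4.08,2
2017-06,PM2.5,34.33,14.12,3.46,1
2017-07,PM2.5,30.94,10.37,2.33,1
2017-08,PM2.5,25.03,9.1,6.32,1
2017-09,PM2.5,31.97,12.32,1.96,1
2017-10,PM2.5,51.94,33.77,1.28,2
2016-11,PM10,107.45,48.57,29.08,2
2016-12,PM10,133.52,63.7,7.35,2
2017-01,PM10,128.03,64.97,12.23,2
2017-02,PM10,95.75,42.97,3.16,2
2017-03,PM10,124.23,55.18,17.52,2
2017-04,PM10,104.13,34.35,10.86,2
2017-05,PM10,107.03,60.05,32.71,2
2017-06,PM10,64,24.06,6.25,2
2017-07,PM10,51.97,15.16,0.93,2
2017-08,PM10,46,14.64,7.64,1
2017-09,PM10,62.2,16.24,2.6,2
2017-10,PM10,88.9,44.89,6.9,2
2016-11,SO2,71.36,29.07,12.65,2
2016-12,SO2,95.65,39.7,7.42,2
2017-01,SO2,98.77,41.92,16.19,2
2017-02,SO2,70.96,31.64,5.87,2
2017-03,SO2,54.1,23.1,8.11,2
2017-04,SO2,23.93,11.27,3.23,1
2017-05,SO2,14.13,4.86,1.78,1
2017-06,SO2,18.3,6.37,0.93,1
2017-07,SO2,12.23,5.4,0.78,1
2017-08,SO2,14.97,4.49,2.03,1
2017-09,SO2,22.57,7.02,1.78,1
2017-10,SO2,24.74,12.46,3.97,1
2016-11,CO,1.01,0.38,0.08,1
2016-12,CO,1.44,0.65,0.22,1
2017-01,CO,1.39,0.69,0.26,1
2017-02,CO,1.07,0.52,0.02,1
2017-03,CO,1.02,0.42,0.12,1
2017-04,CO,0.77,0.28,0.07,1
2017-05,CO,0.63,0.2,0.02,1
2017-06,CO,0.77,0.3,0.05,1
2017-07,CO,0.74,0.19,0.07,1
2017-08,CO,0.83,0.26,0.1,1
2017-09,CO,0.93,0.29,0.08,1
2017-10,CO,1.1,0.6,0.13,1
2016-11,NO2,48.46,11.17,2.21,2
2016-12,NO2,57.42,16.1,6.21,2
2017-01,NO2,54.81,20.87,8.33,2
2017-02,NO2,46.14,16.38,6.26,2
2017-03,NO2,53.71,17.76,6.26,2
2017-04,NO2,36.37,9.23,0.97,1
2017-05,NO2,29.13,8.11,0.62,1
2017-06,NO2,33.17,8.06,1.35,1
2017-07,NO2,27.58,10.45,2.11,1
2017-08,NO2,29.74,6.38,3.59,1
2017-09,NO2,37.93,7.51,0.82,1
2017-10,NO2,47.74,18.87,4.93,2
2016-11,O3,57.9,12.81,6.1,1
2016-12,O3,39.77,14.41,2.56,1
2017-01,O3,50,16.17,4.49,1
2017-02,O3,75.68,12.64,7.94,1
2017-03,O3,109.35,18.6,6.92,2
2017-04,O3,119.63,29.06,5.34,2
2017-05,O3,144.16,47.51,9.38,2
2017-06,O3,156.13,52.78,13.02,2
2017-07,O3,155.23,38.49,12.38,2
2017-08,O3,106.87,38.48,12.15,2
2017-09,O3,102.93,32.17,11.98,2
2017-10,O3,72.94,23.59,8.55,1
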