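energy,point_id,x_cm,y_cm,dose_cgy,source
6MV,A,-5.6,3,30.6,A16
6MV,B,0,3,37.1,A16
6MV,C,5.6,3,21.1,A16
6MV,D,-5.6,0,131.9,A16
6MV,E,0,0,131.8,A16
6MV,F,5.6,0,134.3,A16
6MV,A,-5.6,3,21.7,MatriXX
6MV,B,0,3,34.5,MatriXX
6MV,C,5.6,3,22.0,MatriXX
6MV,D,-5.6,0,131.1,MatriXX
6MV,E,0,0,130.3,MatriXX
6MV,F,5.6,0,131.4,MatriXX
6MV,A,-5.6,3,30.2,EDR2
6MV,B,0,3,55.8,EDR2
6MV,C,5.6,3,27.2,EDR2
6MV,D,-5.6,0,131.5,EDR2
6MV,E,0,0,133.5,EDR2
6MV,F,5.6,0,135.6,EDR2
6MV,A,-5.6,3,30.2,tps
6MV,B,0,3,33.5,tps
6MV,C,5.6,3,30.9,tps
6MV,D,-5.6,0,134.7,tps
6MV,E,0,0,132.8,tps
6MV,F,5.6,0,135.1,tps
10MV,A,-5.6,3,35.3,A16
10MV,B,0,3,37.1,A16
10MV,C,5.6,3,24.1,A16
10MV,D,-5.6,0,145.0,A16
10MV,E,0,0,141.4,A16
10MV,F,5.6,0,143.9,A16
10MV,A,-5.6,3,24.2,MatriXX
10MV,B,0,3,40.6,MatriXX
10MV,C,5.6,3,26.1,MatriXX
10MV,D,-5.6,0,142.5,MatriXX
10MV,E,0,0,139.7,MatriXX
10MV,F,5.6,0,142.2,MatriXX
10MV,A,-5.6,3,35.8,EDR2
10MV,B,0,3,58.4,EDR2
10MV,C,5.6,3,35.8,EDR2
10MV,D,-5.6,0,148.6,EDR2
10MV,E,0,0,144.2,EDR2
10MV,F,5.6,0,146.4,EDR2
10MV,A,-5.6,3,30.1,tps
10MV,B,0,3,34.5,tps
10MV,C,5.6,3,30.8,tps
10MV,D,-5.6,0,146.0,tps
10MV,E,0,0,142.6,tps
10MV,F,5.6,0,146.6,tps
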