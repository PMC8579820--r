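species,MAT,TS,maxTWaM,minTCM,mTWaQ,mTCQ,AP,PDM,PS,PWeQ,PDQ
bustillosii,8.95,550.98,22.47,-3.14,16.46,1.44,296.82,9.92,46.43,138.73,34.37
uspallatensis,6.85,461.27,18.93,-5.12,12.84,0.29,231.12,4.25,76.38,136.33,15.67
bifrons,9.07,362.02,19.67,-2.44,13.63,3.71,65.73,1.80,107.59,38.14,6.48
checoensis,12.55,339.44,22.74,0.75,16.69,7.39,68.57,0.79,130.34,45.95,2.70
farnesiana,14.5,396.2,24.7,3,19.5,8.8,73,0,129,65,0
geranioides,13.84,388.00,24.40,1.78,18.64,8.04,57.76,0.01,120.07,45.15,1.98
glutinosa,11.20,339.74,21.16,0.28,15.51,6.16,56.69,1.69,102.23,29.73,6.18
tomentosa,8.80,318.30,19.20,-3.22,12.64,3.89,43.43,0.57,131.25,31.36,1.92
potentillifolia,8.48,421.00,19.68,-3.58,13.77,2.37,78.80,0.28,128.18,65.66,1.10
radiata,16.45,319.33,25.34,6.38,20.50,11.80,80.74,0.21,122.80,62.40,1.25
robusta,13.63,548.34,26.32,1.09,21.03,5.90,450.47,13.53,47.25,193.85,45.57
adscendens_viridis,10.70,468.84,22.41,-1.98,16.63,3.88,220.93,0.53,102.68,152.15,5.45
adscendens_adscendens,7.83,537.23,20.92,-4.73,14.92,0.55,332.44,0.97,105.72,237.26,6.21
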