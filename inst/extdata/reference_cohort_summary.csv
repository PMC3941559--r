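section,variable,unit,mean,sd,min,max
anthropometric,age,years,15.4,1.0,14.0,17.0
anthropometric,body_mass,kg,61.3,12.3,43.5,87.0
anthropometric,height,m,1.66,0.1,1.52,1.87
anthropometric,bmi,kg/m2,22.1,3.5,17.6,32.3
anthropometric,thorax,cm,25.5,1.9,21.5,29.5
pulmonary,FEV1,l,3.22,0.82,1.77,5.16
pulmonary,FVC,l,3.87,0.91,2.39,5.81
pulmonary,PEF,l/s,6.50,2.41,2.84,12.15
pulmonary,DI,l,3.59,0.91,2.05,5.40
expiration,UT,l,7.32,2.44,4.30,15.22
expiration,LT,l,5.90,2.21,2.51,11.12
expiration,TT,l,13.21,4.14,7.82,26.34
expiration,UA,l,2.56,0.87,0.91,5.19
expiration,LA,l,3.56,1.56,0.74,8.41
expiration,TA,l,6.12,2.2,2.53,13.18
expiration,thoracoabdominal,l,19.33,6.18,10.36,39.52
inspiration,UT,l,8.41,2.62,4.93,15.17
inspiration,LT,l,7.65,3.25,3.05,17.04
inspiration,TT,l,16.06,5.24,9.75,30.79
inspiration,UA,l,3.16,1.19,1.13,6.87
inspiration,LA,l,3.86,1.83,0.87,9.39
inspiration,TA,l,7.02,2.75,2.66,15.69
inspiration,thoracoabdominal,l,23.08,7.77,12.41,46.31
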