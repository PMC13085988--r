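patient_id,age,gcs,aptt,creatinine,sodium,ntprobnp,procalcitonin,crp,wbc,hematocrit,platelets,pao2,fio2,lactic_acid,sbp,dbp,albumin,bilirubin,pt,gender,outcome
train1,38,14,43.5,352,143.3,10000,100.0,200.0,13.69,14.9,26,109.0,21,0.9,124,84,24.2,68.2,14.8,female,dies
train2,84,15,52.0,220,145.2,8264,100.0,155.7,16.11,37.4,42,82.8,21,4.0,101,59,29.9,5.3,16.4,male,survives
train3,78,11,40.0,126,143.4,2193,0.81,95.4,2.06,22.7,89,80.9,33,2.7,116,66,27.0,13.8,14.8,male,survives
train4,53,15,44.1,88,141.3,1935,4.05,132.6,11.23,35.2,140,86.0,29,2.5,95,55,29.6,167.9,16.7,female,survives
train5,56,14,47.1,53,131.1,959,11.63,354.1,0.55,24.4,46,143.0,33,1.3,92,57,28.3,5.2,14.2,female,survives
train6,88,15,41.5,138,143.2,2603,0.68,227.5,12.94,30.7,175,103.0,40,3.4,124,56,25.7,115.9,16.4,male,survives
train7,70,15,49.1,269,145.3,5719,27.29,240.2,21.83,39.3,104,128.0,33,3.4,110,67,24.8,24.1,16.8,male,survives
train8,22,11,41.9,57,139.8,4968,0.78,138.3,8.86,19.9,199,74.4,21,1.8,108,79,27.1,39.1,14.1,female,survives
train9,50,14,39.4,100,142.8,73,2.06,116.6,14.2,38.9,266,71.8,21,1.5,95,51,37.5,11.3,16.0,male,survives
train10,63,15,46.6,69,150.7,781,100.0,228.4,9.37,34.2,76,100.0,21,1.0,138,77,26.8,15.6,16.5,female,survives
test1,79,15,34.2,166,139.8,3012,2.49,200.0,19.45,37.6,181,60.7,21,1.4,140,60,25.4,14.7,14.9,male,
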