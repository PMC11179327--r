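group,n,variable,mean,sd
oa_male,22,age,73.5,7.6
oa_male,22,height_cm,162.8,6.4
oa_male,22,weight_kg,66.0,8.6
oa_male,22,bmi,24.9,2.9
oa_male,22,fta,186.8,2.7
oa_male,22,mct,12.2,4.1
oa_female,38,age,73.6,6.5
oa_female,38,height_cm,148.9,5.5
oa_female,38,weight_kg,59.0,8.6
oa_female,38,bmi,26.6,3.7
oa_female,38,fta,189.3,4.5
oa_female,38,mct,12.3,4.5
healthy_male,28,age,71.3,6.1
healthy_male,28,height_cm,166.2,4.6
healthy_male,28,weight_kg,63.6,7.3
healthy_male,28,bmi,23.0,2.1
healthy_male,28,fta,178.5,2.5
healthy_male,28,mct,9.3,2.7
healthy_female,25,age,67.7,5.5
healthy_female,25,height_cm,155.4,5.3
healthy_female,25,weight_kg,48.3,5.0
healthy_female,25,bmi,20.0,1.6
healthy_female,25,fta,175.4,2.1
healthy_female,25,mct,6.9,2.3
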