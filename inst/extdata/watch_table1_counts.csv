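margin_kg,visit,bmi_category,zone,count
2,19,underweight,below,0
2,19,underweight,within,1
2,19,underweight,above,6
2,19,normal,below,12
2,19,normal,within,34
2,19,normal,above,22
2,19,overweight,below,4
2,19,overweight,within,9
2,19,overweight,above,16
2,19,obese,below,11
2,19,obese,within,10
2,19,obese,above,6
2,24,underweight,below,0
2,24,underweight,within,1
2,24,underweight,above,6
2,24,normal,below,8
2,24,normal,within,37
2,24,normal,above,23
2,24,overweight,below,3
2,24,overweight,within,10
2,24,overweight,above,16
2,24,obese,below,8
2,24,obese,within,11
2,24,obese,above,8
2,30,underweight,below,0
2,30,underweight,within,1
2,30,underweight,above,6
2,30,normal,below,7
2,30,normal,within,36
2,30,normal,above,25
2,30,overweight,below,1
2,30,overweight,within,13
2,30,overweight,above,15
2,30,obese,below,7
2,30,obese,within,10
2,30,obese,above,10
2,36,underweight,below,0
2,36,underweight,within,2
2,36,underweight,above,5
2,36,normal,below,6
2,36,normal,within,40
2,36,normal,above,22
2,36,overweight,below,3
2,36,overweight,within,11
2,36,overweight,above,15
2,36,obese,below,6
2,36,obese,within,11
2,36,obese,above,10
5,19,underweight,below,0
5,19,underweight,within,4
5,19,underweight,above,3
5,19,normal,below,0
5,19,normal,within,59
5,19,normal,above,9
5,19,overweight,below,1
5,19,overweight,within,25
5,19,overweight,above,3
5,19,obese,below,4
5,19,obese,within,20
5,19,obese,above,3
5,24,underweight,below,0
5,24,underweight,within,4
5,24,underweight,above,3
5,24,normal,below,0
5,24,normal,within,55
5,24,normal,above,13
5,24,overweight,below,0
5,24,overweight,within,24
5,24,overweight,above,5
5,24,obese,below,5
5,24,obese,within,18
5,24,obese,above,4
5,30,underweight,below,0
5,30,underweight,within,4
5,30,underweight,above,3
5,30,normal,below,0
5,30,normal,within,55
5,30,normal,above,13
5,30,overweight,below,0
5,30,overweight,within,20
5,30,overweight,above,9
5,30,obese,below,3
5,30,obese,within,17
5,30,obese,above,7
5,36,underweight,below,0
5,36,underweight,within,4
5,36,underweight,above,3
5,36,normal,below,0
5,36,normal,within,54
5,36,normal,above,14
5,36,overweight,below,0
5,36,overweight,within,19
5,36,overweight,above,10
5,36,obese,below,3
5,36,obese,within,17
5,36,obese,above,7
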