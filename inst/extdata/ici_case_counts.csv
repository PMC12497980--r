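drug,variable,category,count
atezolizumab,sex,female,47
atezolizumab,sex,male,71
atezolizumab,sex,missing,44
atezolizumab,weight,<50 kg,4
atezolizumab,weight,>100 kg,4
atezolizumab,weight,50~100 kg,54
atezolizumab,weight,missing,100
atezolizumab,age,<18 years,2
atezolizumab,age,>85 years,3
atezolizumab,age,18~64.9 years,39
atezolizumab,age,65~85 years,52
atezolizumab,age,missing,66
atezolizumab,occupation,consumer,3
atezolizumab,occupation,health_professional,34
atezolizumab,occupation,physician,121
atezolizumab,occupation,pharmacist,4
atezolizumab,occupation,missing,0
atezolizumab,country,US,41
atezolizumab,country,JP,57
atezolizumab,country,DE,5
atezolizumab,country,FR,9
atezolizumab,country,CN,5
atezolizumab,country,XX,45
atezolizumab,outcome,death,26
atezolizumab,outcome,other_outcome,136
durvalumab,sex,female,27
durvalumab,sex,male,49
durvalumab,sex,missing,6
durvalumab,weight,<50 kg,1
durvalumab,weight,50~100 kg,27
durvalumab,weight,missing,54
durvalumab,age,18~64.9 years,25
durvalumab,age,65~85 years,24
durvalumab,age,missing,33
durvalumab,occupation,consumer,4
durvalumab,occupation,health_professional,3
durvalumab,occupation,physician,64
durvalumab,occupation,pharmacist,3
durvalumab,occupation,missing,8
durvalumab,country,US,17
durvalumab,country,JP,18
durvalumab,country,DE,2
durvalumab,country,FR,8
durvalumab,country,CN,9
durvalumab,country,XX,28
durvalumab,outcome,death,10
durvalumab,outcome,other_outcome,72
avelumab,sex,female,3
avelumab,sex,male,11
avelumab,sex,missing,1
avelumab,weight,<50 kg,2
avelumab,weight,>100 kg,2
avelumab,weight,50~100 kg,4
avelumab,weight,missing,7
avelumab,age,>85 years,1
avelumab,age,18~64.9 years,3
avelumab,age,65~85 years,10
avelumab,age,missing,1
avelumab,occupation,health_professional,1
avelumab,occupation,physician,14
avelumab,country,US,3
avelumab,country,JP,3
avelumab,country,DE,1
avelumab,country,FR,1
avelumab,country,XX,7
avelumab,outcome,death,3
avelumab,outcome,other_outcome,8
avelumab,outcome,none,4
tislelizumab,sex,male,8
tislelizumab,weight,>100 kg,8
tislelizumab,age,missing,8
tislelizumab,occupation,health_professional,6
tislelizumab,occupation,pharmacist,2
tislelizumab,country,CN,8
tislelizumab,outcome,other_outcome,8
pembrolizumab,sex,female,147
pembrolizumab,sex,male,166
pembrolizumab,sex,missing,11
pembrolizumab,weight,<50 kg,15
pembrolizumab,weight,>100 kg,7
pembrolizumab,weight,50~100 kg,73
pembrolizumab,weight,missing,229
pembrolizumab,age,<18 years,7
pembrolizumab,age,>85 years,1
pembrolizumab,age,18~64.9 years,131
pembrolizumab,age,65~85 years,118
pembrolizumab,age,missing,67
pembrolizumab,occupation,consumer,89
pembrolizumab,occupation,health_professional,44
pembrolizumab,occupation,physician,164
pembrolizumab,occupation,pharmacist,17
pembrolizumab,occupation,lawyer,1
pembrolizumab,occupation,other,9
pembrolizumab,country,US,114
pembrolizumab,country,JP,111
pembrolizumab,country,DE,21
pembrolizumab,country,FR,22
pembrolizumab,country,CN,3
pembrolizumab,country,XX,53
pembrolizumab,outcome,death,44
pembrolizumab,outcome,other_outcome,280
nivolumab,sex,female,146
nivolumab,sex,male,223
nivolumab,sex,missing,44
nivolumab,weight,<50 kg,13
nivolumab,weight,>100 kg,11
nivolumab,weight,50~100 kg,131
nivolumab,weight,missing,258
nivolumab,age,<18 years,2
nivolumab,age,>85 years,1
nivolumab,age,18~64.9 years,179
nivolumab,age,65~85 years,137
nivolumab,age,missing,94
nivolumab,occupation,consumer,43
nivolumab,occupation,health_professional,97
nivolumab,occupation,physician,176
nivolumab,occupation,pharmacist,24
nivolumab,occupation,other,73
nivolumab,country,US,145
nivolumab,country,JP,85
nivolumab,country,DE,51
nivolumab,country,FR,40
nivolumab,country,CN,4
nivolumab,country,XX,88
nivolumab,outcome,death,65
nivolumab,outcome,other_outcome,348
ipilimumab,sex,female,46
ipilimumab,sex,male,93
ipilimumab,sex,missing,8
ipilimumab,weight,<50 kg,6
ipilimumab,weight,>100 kg,4
ipilimumab,weight,50~100 kg,52
ipilimumab,weight,missing,85
ipilimumab,age,<18 years,2
ipilimumab,age,>85 years,1
ipilimumab,age,18~64.9 years,72
ipilimumab,age,65~85 years,50
ipilimumab,age,missing,22
ipilimumab,occupation,consumer,20
ipilimumab,occupation,health_professional,12
ipilimumab,occupation,physician,72
ipilimumab,occupation,pharmacist,2
ipilimumab,occupation,other,40
ipilimumab,occupation,missing,1
ipilimumab,country,US,52
ipilimumab,country,JP,56
ipilimumab,country,DE,9
ipilimumab,country,FR,6
ipilimumab,country,XX,24
ipilimumab,outcome,death,14
ipilimumab,outcome,other_outcome,133
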