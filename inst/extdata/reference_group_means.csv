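measurand,group,region,mean,SD
nB.Ar,0.0mm,anterior,88.1,21.2
nB.Ar,0.0mm,posterior,48.8,27.3
nB.Ar,0.0mm,total,136.9,16.0
nB.Ar,0.2mm,anterior,70.9,32.3
nB.Ar,0.2mm,posterior,63.1,25.4
nB.Ar,0.2mm,total,134.0,20.4
nB.Ar,0.4mm,anterior,111.7,38.4
nB.Ar,0.4mm,posterior,58.8,28.1
nB.Ar,0.4mm,total,170.5,53.1
nB.Ar,0.8mm,anterior,103.8,36.4
nB.Ar,0.8mm,posterior,56.8,25.5
nB.Ar,0.8mm,total,160.6,55.8
nB.Ar,control,anterior,70.7,44.0
nB.Ar,control,posterior,34.4,9.1
nB.Ar,control,total,105.1,43.6
Cg.Ar,0.0mm,anterior,5.2,4.4
Cg.Ar,0.0mm,posterior,1.3,2.4
Cg.Ar,0.0mm,total,6.6,4.5
Cg.Ar,0.2mm,anterior,5.9,4.6
Cg.Ar,0.2mm,posterior,3.5,1.9
Cg.Ar,0.2mm,total,9.4,5.7
Cg.Ar,0.4mm,anterior,8.7,9.3
Cg.Ar,0.4mm,posterior,2.4,3.3
Cg.Ar,0.4mm,total,11.1,10.1
Cg.Ar,0.8mm,anterior,5.6,3.0
Cg.Ar,0.8mm,posterior,2.4,2.1
Cg.Ar,0.8mm,total,7.9,4.4
Cg.Ar,control,anterior,0.3,0.3
Cg.Ar,control,posterior,0.0,0.0
Cg.Ar,control,total,0.3,0.3
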