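network,algorithm,accuracy,n_selected
DarkNet-19,MPA,0.906,267
DarkNet-19,ASOA,0.895,516
DarkNet-19,HHOA,0.894,172
DarkNet-19,BOA,0.88,413
DarkNet-19,WOA,0.895,304
DarkNet-19,GWOA,0.909,303
DarkNet-19,BA,0.894,494
DarkNet-19,FA,0.892,447
DarkNet-53,MPA,0.93,732
DarkNet-53,ASOA,0.922,504
DarkNet-53,HHOA,0.923,575
DarkNet-53,BOA,0.913,481
DarkNet-53,WOA,0.918,712
DarkNet-53,GWOA,0.934,362
DarkNet-53,BA,0.913,491
DarkNet-53,FA,0.92,521
DenseNet-201,MPA,0.93,939
DenseNet-201,ASOA,0.916,979
DenseNet-201,HHOA,0.922,1270
DenseNet-201,BOA,0.894,912
DenseNet-201,WOA,0.909,970
DenseNet-201,GWOA,0.946,651
DenseNet-201,BA,0.908,964
DenseNet-201,FA,0.918,950
EfficientNet-b0,MPA,0.944,821
EfficientNet-b0,ASOA,0.949,641
EfficientNet-b0,HHOA,0.939,862
EfficientNet-b0,BOA,0.925,551
EfficientNet-b0,WOA,0.944,654
EfficientNet-b0,GWOA,0.939,451
EfficientNet-b0,BA,0.934,669
EfficientNet-b0,FA,0.936,621
GoogLeNet365,MPA,0.894,388
GoogLeNet365,ASOA,0.901,499
GoogLeNet365,HHOA,0.885,487
GoogLeNet365,BOA,0.878,472
GoogLeNet365,WOA,0.882,542
GoogLeNet365,GWOA,0.899,401
GoogLeNet365,BA,0.887,522
GoogLeNet365,FA,0.887,479
GoogLeNet,MPA,0.889,667
GoogLeNet,ASOA,0.873,531
GoogLeNet,HHOA,0.883,501
GoogLeNet,BOA,0.852,521
GoogLeNet,WOA,0.873,690
GoogLeNet,GWOA,0.895,338
GoogLeNet,BA,0.864,518
GoogLeNet,FA,0.871,493
Inception-ResNet-v2,MPA,0.915,533
Inception-ResNet-v2,ASOA,0.909,753
Inception-ResNet-v2,HHOA,0.908,739
Inception-ResNet-v2,BOA,0.909,802
Inception-ResNet-v2,WOA,0.902,782
Inception-ResNet-v2,GWOA,0.925,488
Inception-ResNet-v2,BA,0.904,754
Inception-ResNet-v2,FA,0.908,763
Inception-v3,MPA,0.904,878
Inception-v3,ASOA,0.911,997
Inception-v3,HHOA,0.908,1023
Inception-v3,BOA,0.895,764
Inception-v3,WOA,0.895,1174
Inception-v3,GWOA,0.923,768
Inception-v3,BA,0.901,990
Inception-v3,FA,0.895,966
MobileNet-v2,MPA,0.913,812
MobileNet-v2,ASOA,0.902,647
MobileNet-v2,HHOA,0.89,770
MobileNet-v2,BOA,0.883,623
MobileNet-v2,WOA,0.887,738
MobileNet-v2,GWOA,0.894,512
MobileNet-v2,BA,0.892,659
MobileNet-v2,FA,0.897,633
NASNet-Mobile,MPA,0.885,575
NASNet-Mobile,ASOA,0.869,505
NASNet-Mobile,HHOA,0.871,714
NASNet-Mobile,BOA,0.864,461
NASNet-Mobile,WOA,0.873,854
NASNet-Mobile,GWOA,0.887,364
NASNet-Mobile,BA,0.866,497
NASNet-Mobile,FA,0.871,549
ResNet-101,MPA,0.925,1279
ResNet-101,ASOA,0.927,1057
ResNet-101,HHOA,0.915,1231
ResNet-101,BOA,0.923,927
ResNet-101,WOA,0.915,1536
ResNet-101,GWOA,0.927,826
ResNet-101,BA,0.913,985
ResNet-101,FA,0.911,1005
ResNet-50,MPA,0.934,1228
ResNet-50,ASOA,0.937,1013
ResNet-50,HHOA,0.939,1254
ResNet-50,BOA,0.916,877
ResNet-50,WOA,0.932,1068
ResNet-50,GWOA,0.939,692
ResNet-50,BA,0.927,1017
ResNet-50,FA,0.934,1016
ResNet-18,MPA,0.878,274
ResNet-18,ASOA,0.876,242
ResNet-18,HHOA,0.875,315
ResNet-18,BOA,0.854,214
ResNet-18,WOA,0.864,428
ResNet-18,GWOA,0.887,210
ResNet-18,BA,0.88,242
ResNet-18,FA,0.873,233
ShuffleNet,MPA,0.916,217
ShuffleNet,ASOA,0.904,274
ShuffleNet,HHOA,0.911,374
ShuffleNet,BOA,0.887,271
ShuffleNet,WOA,0.895,321
ShuffleNet,GWOA,0.918,218
ShuffleNet,BA,0.894,286
ShuffleNet,FA,0.901,256
SqueezeNet,MPA,0.904,519
SqueezeNet,ASOA,0.913,499
SqueezeNet,HHOA,0.902,619
SqueezeNet,BOA,0.885,516
SqueezeNet,WOA,0.894,852
SqueezeNet,GWOA,0.901,385
SqueezeNet,BA,0.889,485
SqueezeNet,FA,0.89,483
Xception,MPA,0.92,809
Xception,ASOA,0.929,1035
Xception,HHOA,0.916,1149
Xception,BOA,0.908,889
Xception,WOA,0.911,978
Xception,GWOA,0.93,775
Xception,BA,0.916,1002
Xception,FA,0.915,1009
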