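channel,A,B,C,D,E,F
Fp1,0.1100624446,0.1818887866,0.2374439905,-0.0997337379,-0.0974914006,0.3551104548
AF3,0.0409703201,0.195559874,0.1923700508,-0.0695263185,-0.095626707,0.2329445716
AF7,-0.0284522516,0.2177492143,0.1539552549,-0.1271355792,-0.0961468584,0.0150571009
F1,0.0467855011,0.1357106401,0.1484241456,0.088430426,-0.0894535315,0.2234173262
F3,0.0023229316,0.1712290286,0.1411498415,0.0051931362,-0.0904314381,0.1450624298
F5,-0.0363244568,0.195559874,0.1295061943,-0.0695263185,-0.0917298311,0.0587564453
F7,-0.0655484004,0.2059369278,0.1141780154,-0.1134914797,-0.0930392017,-0.0084619706
FC1,0.0023229316,0.0958565206,0.0798493667,0.2259620861,-0.0723675367,0.0763061681
FC3,-0.0421396379,0.1357106401,0.0761013135,0.088430426,-0.0762882004,0.0380324785
Fp2,0.1818887866,0.1100624446,0.2374439905,-0.0997337379,-0.0974914006,0.3551104548
AF4,0.195559874,0.0409703201,0.1923700508,-0.0695263185,-0.095626707,0.2329445716
AF8,0.2177492143,-0.0284522516,0.1539552549,-0.1271355792,-0.0961468584,0.0150571009
F2,0.1357106401,0.0467855011,0.1484241456,0.088430426,-0.0894535315,0.2234173262
F4,0.1712290286,0.0023229316,0.1411498415,0.0051931362,-0.0904314381,0.1450624298
F6,0.195559874,-0.0363244568,0.1295061943,-0.0695263185,-0.0917298311,0.0587564453
F8,0.2059369278,-0.0655484004,0.1141780154,-0.1134914797,-0.0930392017,-0.0084619706
FC2,0.0958565206,0.0023229316,0.0798493667,0.2259620861,-0.0723675367,0.0763061681
FC4,0.1357106401,-0.0421396379,0.0761013135,0.088430426,-0.0762882004,0.0380324785
FC5,-0.0792230529,0.1654149007,0.0700998458,-0.0317230528,-0.081245546,-0.0057439501
C1,-0.0452273415,0.0498732047,0.0037784815,0.2901147242,-0.028333727,-0.0224277951
C3,-0.0881230626,0.0927689258,0.0037784815,0.1267195796,-0.0415293691,-0.0365860581
C5,-0.1221652996,0.1268111628,0.0037784815,-0.014716268,-0.0573575653,-0.0535689198
FC6,0.1654149007,-0.0792230529,0.0700998458,-0.0317230528,-0.081245546,-0.0057439501
C2,0.0498732047,-0.0452273415,0.0037784815,0.2901147242,-0.028333727,-0.0224277951
C4,0.0927689258,-0.0881230626,0.0037784815,0.1267195796,-0.0415293691,-0.0365860581
C6,0.1268111628,-0.1221652996,0.0037784815,-0.014716268,-0.0573575653,-0.0535689198
FT7,-0.1054165813,0.1818887866,0.0621948587,-0.0997337379,-0.0859333228,-0.0417115877
T7,-0.1440217611,0.1486676244,0.0037784815,-0.0937220327,-0.0712660733,-0.0684920523
TP7,-0.1772429233,0.1100624446,-0.0546378958,-0.0997337379,-0.0463064137,-0.0842292763
CP5,-0.1607690374,0.0838689161,-0.0625428829,-0.0317230528,-0.0127842174,-0.0791995267
P5,-0.1909140108,0.0409703201,-0.1219492314,-0.0695263185,0.0473307934,-0.0904486394
FT8,0.1818887866,-0.1054165813,0.0621948587,-0.0997337379,-0.0859333228,-0.0417115877
T8,0.1486676244,-0.1440217611,0.0037784815,-0.0937220327,-0.0712660733,-0.0684920523
TP8,0.1100624446,-0.1772429233,-0.0546378958,-0.0997337379,-0.0463064137,-0.0842292763
CP6,0.0838689161,-0.1607690374,-0.0625428829,-0.0317230528,-0.0127842174,-0.0791995267
P6,0.0409703201,-0.1909140108,-0.1219492314,-0.0695263185,0.0473307934,-0.0904486394
CP1,-0.0912106573,0.0023229316,-0.0722924038,0.2259620861,0.0636873097,-0.0696738673
CP3,-0.1310647769,0.0467855011,-0.0685443506,0.088430426,0.0280158499,-0.073880543
P1,-0.1310647769,-0.0421396379,-0.1408671827,0.088430426,0.2007963737,-0.0880062839
P3,-0.1665831654,0.0023229316,-0.1335928786,0.0051931362,0.1277688301,-0.0890555287
CP2,0.0023229316,-0.0912106573,-0.0722924038,0.2259620861,0.0636873097,-0.0696738673
CP4,0.0467855011,-0.1310647769,-0.0685443506,0.088430426,0.0280158499,-0.073880543
P2,-0.0421396379,-0.1310647769,-0.1408671827,0.088430426,0.2007963737,-0.0880062839
P4,0.0023229316,-0.1665831654,-0.1335928786,0.0051931362,0.1277688301,-0.0890555287
PO3,-0.1909140108,-0.0363244568,-0.1848130879,-0.0695263185,0.2096758612,-0.0946297921
PO7,-0.213103351,0.0330981149,-0.146398292,-0.1271355792,0.0066025693,-0.0951878885
P7,-0.2012910645,0.0701942637,-0.1066210524,-0.1134914797,-0.0153174395,-0.0918535284
O1,-0.1772429233,-0.1054165813,-0.2298870276,-0.0997337379,0.3235356807,-0.0966305149
PO4,-0.0363244568,-0.1909140108,-0.1848130879,-0.0695263185,0.2096758612,-0.0946297921
PO8,0.0330981149,-0.213103351,-0.146398292,-0.1271355792,0.0066025693,-0.0951878885
P8,0.0701942637,-0.2012910645,-0.1066210524,-0.1134914797,-0.0153174395,-0.0918535284
O2,-0.1054165813,-0.1772429233,-0.2298870276,-0.0997337379,0.3235356807,-0.0966305149
AFz,0.1268111628,0.1268111628,0.2062710845,-0.014716268,-0.0953620658,0.3971248728
Fz,0.0927689258,0.0927689258,0.1508979692,0.1267195796,-0.0890872119,0.2557785644
FCz,0.0498732047,0.0498732047,0.0811237734,0.2901147242,-0.0708600429,0.0918090432
CPz,-0.0452273415,-0.0452273415,-0.0735668105,0.2901147242,0.0781361436,-0.068056402
Pz,-0.0881230626,-0.0881230626,-0.1433410063,0.1267195796,0.2309573699,-0.0876132414
POz,-0.1221652996,-0.1221652996,-0.1987141216,-0.014716268,0.3626935365,-0.0943458453
Oz,-0.1440217611,-0.1440217611,-0.2342658501,-0.0937220327,0.3706518423,-0.0966273758
FT9,-0.1183288672,0.1833006299,0.0528415467,-0.1289723611,-0.0896378073,-0.0657300576
FT10,0.1833006299,-0.1183288672,0.0528415467,-0.1289723611,-0.0896378073,-0.0657300576
TP9,-0.1786547667,0.1229747305,-0.0452845838,-0.1289723611,-0.0686918667,-0.0882040027
TP10,0.1229747305,-0.1786547667,-0.0452845838,-0.1289723611,-0.0686918667,-0.0882040027
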