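time,x1_mean,x1_std,x2_mean,x2_std,x3_mean,x3_std
0.0000000000000000,0.69898954923240608,0.0365973664386216521,0.83515299285548250,0.041817435370430679,1.1278147132526499,0.062696752543762668
1.1907512219766323,0.64271880372905854,0.0349495044354491274,0.90690271057307170,0.046977972758287793,1.2426731465481871,0.067247557718730241
2.3815024439532646,0.56048186030383096,0.0312753751690702519,0.96925301777879180,0.050255420162113346,1.5461469154420446,0.072474032864835530
3.5722536659298969,0.52983692949595218,0.0270788247653904850,1.02993881382782471,0.051564472165284037,1.4663672600112596,0.077573344656326662
4.7630048879065292,0.45109229874083440,0.0230968842064435895,1.02120094188537780,0.051216566818683494,1.7380936061111247,0.081934097106584031
5.9537561098831615,0.42209984049942101,0.0195810578094077758,0.98226283767308087,0.049627701351895773,1.5805315249235514,0.085183589564885240
7.1445073318597938,0.34414523020212717,0.0165762556071688549,0.94947596888150521,0.047186317040197198,1.5816630376214853,0.087155246880663326
8.3352585538364252,0.25510281126954004,0.0140545019952455739,0.92983938804655930,0.044213655787163290,1.6486424792920129,0.087834541859500251
9.5260097758130584,0.23025260936359970,0.0119689290102350555,0.86273825329094977,0.040961208821751478,1.7241245221838273,0.087308252670831490
10.7167609977896916,0.19004338223728842,0.0102762716334248924,0.69720142023830711,0.037620790664678910,1.7305885906720793,0.085724305733207967
11.9075122197663230,0.15564850796287913,0.0089494667185298950,0.68532745504561687,0.034338501746202336,1.5972009049258800,0.083262903124567411
13.0982634417429544,0.14600593625238562,0.0079907845228119074,0.58871514942831982,0.031230499169424920,1.5838949828537972,0.080117829542137836
14.2890146637195876,0.13045056913956662,0.0074535211681256396,0.50834952107201847,0.028401877884980973,1.5370774186304572,0.076486952882633713
15.4797658856962208,0.12594594650372351,0.0074813947564319862,0.48616901407607632,0.025972694156294975,1.4135625013814972,0.072572045406234520
16.6705171076728504,0.15231159485649362,0.0083713826294037289,0.42147990807014019,0.024117387800943690,1.3521420863136422,0.068589873492168552
17.8612683296494836,0.19945173068030991,0.0106306881025071687,0.44725116801235099,0.023120129243839115,1.2627672491849686,0.064798025933970160
19.0520195516261168,0.30245926169218645,0.0148763406132063729,0.43438926900320074,0.023419302212876227,1.2001825029728725,0.061535169541564932
20.2427707736027500,0.41904925180731861,0.0212834136717074927,0.48440451051709960,0.025536510162690106,1.1212431339771687,0.059253493032411869
21.4335219955793832,0.56395827654663144,0.0286848465302342488,0.56718131674143746,0.029745771345905146,1.1670751016749712,0.058477006795574771
22.6242732175560128,0.68732651350102292,0.0345240111445341141,0.71037038698275690,0.035594972159440644,1.1360720392082648,0.059615547469432172
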