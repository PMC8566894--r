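sample_id,temperature,salinity,dsb,nitrate,group
S001,29.1507087515011,33.2253289817463,957.162409456906,0.272214401733136,neutral
S002,29.6179503141849,33.9764383873269,1194.75441506466,2.1004508658285,neutral
S003,28.5323764155946,32.9575542654726,1298.56601647848,5.64415720605333,neutral
S004,28.7006793507825,34.3334120016211,607.774017546638,0.86787742729334,neutral
S005,29.646236751863,34.6376155838805,1320.28274487528,1.45511373558615,neutral
S006,29.0473479857026,33.7872867899269,935.0030364009,0.200035132750598,neutral
S007,29.272885426459,34.5710283376065,937.28629340961,2.0626035839517,selected
S008,28.6675536704463,33.8714953408576,526.938371937494,0.825171318278728,selected
S009,29.6005880538131,34.4154744175402,416.991332136032,1.13632219212394,selected
S010,29.0090003954844,33.7481087104586,646.304759967459,0.976977996867366,selected
S011,29.8004984964884,34.2150647724501,1414.90058622853,0.769734974427273,selected
S012,29.2435032935187,34.2359358993162,1837.74297402862,0.652693371107904,selected
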