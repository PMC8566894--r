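(((((OTU_17:0.3782959924,OTU_36:0.3782959924):0.5292875561,((OTU_21:0.518651103,OTU_6:0.518651103):0.3526684529,(OTU_7:0.5035305172,OTU_35:0.5035305172):0.3677890386):0.03626399269):0.8746070067,OTU_28:1.782190555):0.1364126866,((OTU_29:0.1182772378,OTU_23:0.1182772378):0.2022817427,OTU_38:0.3205589805):1.598044261):1.11046454,(((((OTU_27:0.3864939493,OTU_22:0.3864939493):0.2811176572,OTU_5:0.6676116065):1.009606988,((OTU_25:0.2663161313,OTU_3:0.2663161313):1.318206281,(((OTU_19:0.08825588973,OTU_40:0.08825588973):0.5645463673,OTU_18:0.6528022571):0.8891448426,((((OTU_33:0.3890412053,(OTU_2:0.1026817494,OTU_24:0.1026817494):0.2863594558):0.6218096202,(OTU_8:0.9798774082,OTU_26:0.9798774082):0.03097341729):0.3613658526,(((OTU_1:0.27158561,OTU_39:0.27158561):0.1807775098,(OTU_15:0.3314595607,OTU_14:0.3314595607):0.120903559):0.8045328651,((OTU_37:0.2104639419,OTU_20:0.2104639419):0.8291229472,OTU_32:1.039586889):0.2173090957):0.1153206933):0.07809575743,(OTU_13:0.3411900663,(OTU_16:0.03860009401,OTU_9:0.03860009401):0.3025899723):1.109122369):0.09163466416):0.04257531278):0.09269618183):0.8603145882,(OTU_12:0.7450176621,((OTU_34:0.1873170005,OTU_4:0.1873170005):0.2525200058,((OTU_31:0.05947896338,OTU_11:0.05947896338):0.09152352643,OTU_10:0.1510024898):0.2888345166):0.3051806557):1.79251552):0.310280255,OTU_30:2.847813438):0.1812543438);
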