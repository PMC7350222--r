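animal_id,breed,antigen_group,tick_species,larvae_applied,larvae_engorged,larvae_molted,nymphs_applied,nymphs_engorged,nymphs_molted,females_applied,females_engorged,egg_mass_g,larval_mass_per_g_eggs_g
crossbred_Avariegatum_SUB_1,crossbred,Avariegatum_SUB,Rappendiculatus,300,36,24,400,165,88,22,10,2.3391774995484385,0.34210855267824025
crossbred_Avariegatum_SUB_1,crossbred,Avariegatum_SUB,Avariegatum,300,80,46,400,220,149,22,10,3.055008670963988,0.4484897287956876
crossbred_Avariegatum_SUB_1,crossbred,Avariegatum_SUB,Rdecoloratus,NA,NA,NA,NA,NA,NA,300,9,1.8589161881614427,0.202486919492742
crossbred_Avariegatum_SUB_2,crossbred,Avariegatum_SUB,Rappendiculatus,300,9,7,400,174,69,22,11,2.367802803018478,0.5767053855426815
crossbred_Avariegatum_SUB_2,crossbred,Avariegatum_SUB,Avariegatum,300,75,33,400,189,142,22,13,2.7383455920810214,0.47554591053062695
crossbred_Avariegatum_SUB_2,crossbred,Avariegatum_SUB,Rdecoloratus,NA,NA,NA,NA,NA,NA,300,28,5.993396666754893,0.16166234152949138
crossbred_Rappendiculatus_SUB_1,crossbred,Rappendiculatus_SUB,Rappendiculatus,300,147,62,400,220,154,22,12,3.6033332296840435,0.5270257653374557
crossbred_Rappendiculatus_SUB_1,crossbred,Rappendiculatus_SUB,Avariegatum,300,79,31,400,181,104,22,17,3.3867415260763507,0.3028217867564507
crossbred_Rappendiculatus_SUB_1,crossbred,Rappendiculatus_SUB,Rdecoloratus,NA,NA,NA,NA,NA,NA,300,26,5.316701695647369,0.2506746208025942
crossbred_Rappendiculatus_SUB_2,crossbred,Rappendiculatus_SUB,Rappendiculatus,300,80,21,400,171,151,22,2,0.3073625039327875,0.5990682065598804
crossbred_Rappendiculatus_SUB_2,crossbred,Rappendiculatus_SUB,Avariegatum,300,61,20,400,209,106,22,19,5.04638444874596,0.32923860553960826
crossbred_Rappendiculatus_SUB_2,crossbred,Rappendiculatus_SUB,Rdecoloratus,NA,NA,NA,NA,NA,NA,300,28,5.883276905745406,0.20260083217472388
crossbred_Rdecoloratus_SUB_1,crossbred,Rdecoloratus_SUB,Rappendiculatus,300,72,42,400,174,127,22,11,1.5378569228325605,0.4627048042258718
crossbred_Rdecoloratus_SUB_1,crossbred,Rdecoloratus_SUB,Avariegatum,300,59,17,400,188,94,22,17,3.4671425750753215,0.3183328518424555
crossbred_Rdecoloratus_SUB_1,crossbred,Rdecoloratus_SUB,Rdecoloratus,NA,NA,NA,NA,NA,NA,300,47,13.018511547520232,0.20238152711499324
crossbred_Rdecoloratus_SUB_2,crossbred,Rdecoloratus_SUB,Rappendiculatus,300,25,3,400,248,190,22,18,5.114660395832192,0.5034341116619567
crossbred_Rdecoloratus_SUB_2,crossbred,Rdecoloratus_SUB,Avariegatum,300,35,15,400,145,106,22,14,2.573665384886295,0.37178491694105814
crossbred_Rdecoloratus_SUB_2,crossbred,Rdecoloratus_SUB,Rdecoloratus,NA,NA,NA,NA,NA,NA,300,37,7.819704735649685,0.20018599568259543
crossbred_combined_SUB_1,crossbred,combined_SUB,Rappendiculatus,300,120,51,400,156,95,22,20,4.445613974964634,0.5644391368422977
crossbred_combined_SUB_1,crossbred,combined_SUB,Avariegatum,300,129,97,400,125,81,22,19,5.978227247909706,0.4147608328046424
crossbred_combined_SUB_1,crossbred,combined_SUB,Rdecoloratus,NA,NA,NA,NA,NA,NA,300,72,13.27983061705136,0.19384718924936908
crossbred_combined_SUB_2,crossbred,combined_SUB,Rappendiculatus,300,116,50,400,172,110,22,16,3.0000930732416813,0.6733658367805228
crossbred_combined_SUB_2,crossbred,combined_SUB,Avariegatum,300,73,64,400,134,103,22,8,1.3875296281611995,0.4227877030679157
crossbred_combined_SUB_2,crossbred,combined_SUB,Rdecoloratus,NA,NA,NA,NA,NA,NA,300,73,19.193474677303882,0.1565578290954267
crossbred_control_1,crossbred,control,Rappendiculatus,300,111,90,400,282,197,22,14,3.3637169780956615,0.4639012588065659
crossbred_control_1,crossbred,control,Avariegatum,300,161,124,400,180,173,22,12,2.4236773688697952,0.5009797110492208
crossbred_control_1,crossbred,control,Rdecoloratus,NA,NA,NA,NA,NA,NA,300,54,14.023899800650149,0.4186607486198004
crossbred_control_2,crossbred,control,Rappendiculatus,300,221,169,400,97,81,22,14,4.9739018307080345,0.5675334817375676
crossbred_control_2,crossbred,control,Avariegatum,300,190,160,400,152,126,22,19,5.1194256640858615,0.487077600984806
crossbred_control_2,crossbred,control,Rdecoloratus,NA,NA,NA,NA,NA,NA,300,40,9.605781280647594,0.46618583347984704
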