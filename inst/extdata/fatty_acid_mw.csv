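key,common_name,mw_g_per_mol
C12:0,lauric acid,200.32
C14:0,myristic acid,228.38
C15:0,pentadecylic acid,242.40
C16:0,palmitic acid,256.43
C16:1,palmitoleic acid,254.41
C17:0,margaric acid,270.45
C17:1,heptadecenoic acid,268.44
C18:0,stearic acid,284.48
C18:1,oleic/elaidic acid,282.47
C18:2,linoleic acid,280.45
C18:3,linolenic acid,278.44
C20:0,arachidic acid,312.54
C20:1,gondoic acid,310.52
C20:3,eicosatrienoic acid,306.49
C20:4,arachidonic acid,304.47
C20:5,eicosapentaenoic acid,302.46
C22:0,behenic acid,340.59
C22:1,erucic acid,338.58
C22:6,docosahexaenoic acid,328.50
C24:0,lignoceric acid,368.65
C24:1,nervonic acid,366.63
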