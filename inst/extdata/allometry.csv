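species,group,a,b,output_basis,source
Daphnia cucullata,Cladocera,60,3,wet_ug,default_plausible
Daphnia cristata,Cladocera,60,3,wet_ug,default_plausible
Daphnia longispina,Cladocera,65,3,wet_ug,default_plausible
Bosmina longispina,Cladocera,110,3,wet_ug,default_plausible
Bosmina thersites,Cladocera,110,3,wet_ug,default_plausible
Bosmina crassicornis,Cladocera,110,3,wet_ug,default_plausible
Ceriodaphnia quadrangula,Cladocera,80,3,wet_ug,default_plausible
Chydorus sphaericus,Cladocera,90,3,wet_ug,default_plausible
Diaphanosoma brachyurum,Cladocera,50,3,wet_ug,default_plausible
Eudiaptomus gracilis,Copepoda,55,3,wet_ug,default_plausible
Eudiaptomus graciloides,Copepoda,55,3,wet_ug,default_plausible
Eurytemora lacustris,Copepoda,55,3,wet_ug,default_plausible
Heterocope appendiculata,Copepoda,60,3,wet_ug,default_plausible
Mesocyclops leuckarti,Copepoda,50,3,wet_ug,default_plausible
Thermocyclops oithonoides,Copepoda,50,3,wet_ug,default_plausible
Asplanchna priodonta,Rotifera,15,3,wet_ug,default_plausible
Keratella cochlearis,Rotifera,12,3,wet_ug,default_plausible
Conochilus unicornis,Rotifera,12,3,wet_ug,default_plausible
Conochiloides dossuarius,Rotifera,12,3,wet_ug,default_plausible
Pompholyx sulcata,Rotifera,12,3,wet_ug,default_plausible
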