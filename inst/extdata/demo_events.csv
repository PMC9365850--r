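island_id,island_name,country,area_ha,habitation,target_species,status,end_year,primary_method,data_quality,whole_island,feral,purpose_eradication
NZ-001,Motuihe,NZ,179,0,Rattus norvegicus,Successful,1997,Tx,good,TRUE,TRUE,TRUE
NZ-002,Tiritiri Matangi,NZ,220,1-10,Rattus rattus,Successful,1993,Tx,good,TRUE,TRUE,TRUE
AU-001,Macquarie,AU,12785,0,Oryctolagus cuniculus,Successful,2011,Tx,good,TRUE,TRUE,TRUE
US-001,Anacapa,US,296,0,Rattus rattus,Successful,2002,Tx,satisfactory,TRUE,TRUE,TRUE
SC-001,Fregate,SC,219,11-100,Rattus norvegicus,Successful and subsequently reinvaded,1996,Tx,good,TRUE,TRUE,TRUE
MX-001,Isabel,MX,194,0,Felis catus,Successful,1995,Tr,good,TRUE,TRUE,TRUE
GB-001,Lundy,GB,445,11-100,Rattus rattus,To be confirmed,2004,Tx,good,TRUE,TRUE,TRUE
FR-001,Surprise,FR,24,0,Mus musculus,Failed,2005,Tx,satisfactory,TRUE,TRUE,TRUE
EC-001,Seymour Norte,EC,184,0,Rattus rattus,In progress,,Tx,good,TRUE,TRUE,TRUE
NZ-003,Rangitoto,NZ,2311,0,Capra hircus,Successful,1985,H,poor,TRUE,TRUE,TRUE
AU-002,Tasman,AU,120,0,Felis catus,Successful,2010,Tr,good,FALSE,TRUE,TRUE
US-002,San Clemente,US,14569,101-1000,Capra hircus,Successful,1991,H,good,TRUE,TRUE,FALSE
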