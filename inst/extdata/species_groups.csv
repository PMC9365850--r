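species,group,taxon_class,flying
Rattus rattus,rats,mammal,NA
Rattus norvegicus,rats,mammal,NA
Rattus exulans,rats,mammal,NA
Rattus tanezumi,rats,mammal,NA
Capra hircus,ungulates,mammal,NA
Ovis aries,ungulates,mammal,NA
Bos taurus,ungulates,mammal,NA
Equus caballus,ungulates,mammal,NA
Equus asinus,ungulates,mammal,NA
Cervus elaphus,ungulates,mammal,NA
Dama dama,ungulates,mammal,NA
Rangifer tarandus,ungulates,mammal,NA
Odocoileus virginianus,ungulates,mammal,NA
Axis axis,ungulates,mammal,NA
Bubalus bubalis,ungulates,mammal,NA
Camelus dromedarius,ungulates,mammal,NA
Felis catus,cats,mammal,NA
Felis silvestris,cats,mammal,NA
Mus musculus,mice,mammal,NA
Oryctolagus cuniculus,rabbits_hares,mammal,NA
Lepus europaeus,rabbits_hares,mammal,NA
Sylvilagus floridanus,rabbits_hares,mammal,NA
Canis familiaris,dogs_foxes,mammal,NA
Vulpes vulpes,dogs_foxes,mammal,NA
Vulpes lagopus,dogs_foxes,mammal,NA
Cerdocyon thous,dogs_foxes,mammal,NA
Mustela erminea,stoats_weasels_mink_mongoose,mammal,NA
Mustela nivalis,stoats_weasels_mink_mongoose,mammal,NA
Mustela furo,stoats_weasels_mink_mongoose,mammal,NA
Neovison vison,stoats_weasels_mink_mongoose,mammal,NA
Herpestes auropunctatus,stoats_weasels_mink_mongoose,mammal,NA
Trichosurus vulpecula,other_mammals,mammal,NA
Erinaceus europaeus,other_mammals,mammal,NA
Sciurus carolinensis,other_mammals,mammal,NA
Macaca fascicularis,other_mammals,mammal,NA
Procyon lotor,other_mammals,mammal,NA
Nasua nasua,other_mammals,mammal,NA
Dasyprocta leporina,other_mammals,mammal,NA
Cavia porcellus,other_mammals,mammal,NA
Myocastor coypus,other_mammals,mammal,NA
Ondatra zibethicus,other_mammals,mammal,NA
Capromys pilorides,other_mammals,mammal,NA
Sus scrofa,pigs,mammal,NA
Acridotheres tristis,flying_birds,bird,TRUE
Sturnus vulgaris,flying_birds,bird,TRUE
Passer domesticus,flying_birds,bird,TRUE
Columba livia,flying_birds,bird,TRUE
Corvus splendens,flying_birds,bird,TRUE
Pycnonotus cafer,flying_birds,bird,TRUE
Anas platyrhynchos,flying_birds,bird,TRUE
Branta canadensis,flying_birds,bird,TRUE
Circus approximans,flying_birds,bird,TRUE
Zosterops japonicus,flying_birds,bird,TRUE
Gallirallus australis,non_flying_birds,bird,FALSE
Gallus gallus,non_flying_birds,bird,FALSE
Dromaius novaehollandiae,non_flying_birds,bird,FALSE
Rhea americana,non_flying_birds,bird,FALSE
Rhinella marina,frogs_toads,amphibian,NA
Iguana iguana,lizards,reptile,NA
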