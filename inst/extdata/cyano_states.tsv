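# 58 cyanobacterial taxa coded unicellular (sections I-II) / multicellular
# (sections III-V); 16S rDNA study subset, outgroup excluded.
Chamaesiphon_subglobosus_PCC7430	unicellular
Cyanobium_sp_JJ23-1	unicellular
Cyanothece_sp_PCC8801	unicellular
Chroococcus_sp_JJCM	unicellular
Dactylococcopsis_sp	unicellular
Gloeobacter_violaceus_PCC7421	unicellular
Gloeothece_sp_PCC6909-1	unicellular
Microcystis_aeruginosa_038	unicellular
Prochlorococcus_sp_MIT9313	unicellular
Prochloron_sp	unicellular
Radiocystis_sp_JJ30-3	unicellular
Synechococcus_elongatus_PCC6301	unicellular
Synechococcus_sp_CC9605	unicellular
Synechococcus_sp_WH8101	unicellular
Synechocystis_sp_PCC6803	unicellular
Synechocystis_sp_PCC6308	unicellular
Synechocystis_sp_CR_L29	unicellular
Synechococcus_sp_P1	unicellular
Synechococcus_sp_C9	unicellular
Synechococcus_lividus_C1	unicellular
Acaryochloris_sp_JJ8A6	unicellular
Thermosynechococcus_elongatus_BP-1	unicellular
Chroococcidiopsis_sp_CC2	unicellular
Dermocarpa_sp_MBIC10768	unicellular
Dermocarpella_incrassata	unicellular
Myxosarcina_sp_PCC7312	unicellular
Myxosarcina_sp_PCC7325	unicellular
Pleurocapsa_sp_CALU1126	unicellular
Pleurocapsa_sp_PCC7516	unicellular
Arthronema_gygaxiana_UTCC393	multicellular
Arthrospira_platensis_PCC8005	multicellular
Crinalium_magnum_SAG34.87	multicellular
Filamentous_thermophilic_cyanobacterium	multicellular
Geitlerinema_sp_BBD_HS217	multicellular
Halospirulina_sp	multicellular
Leptolyngbya_sp_ANT.LH52.1	multicellular
Lyngbya_aestuarii_PCC7419	multicellular
Microcoleus_chthonoplastes_PCC7420	multicellular
Oscillatoria_sp	multicellular
Oscillatoria_sancta_PCC7515	multicellular
Phormidium_mucicola_IAM_M-221	multicellular
Plectonema_sp_F3	multicellular
Planktothrix_sp_FP1	multicellular
Prochlorothrix_hollandica	multicellular
Pseudanabaena_sp_PCC6802	multicellular
Pseudanabaena_sp_PCC7304	multicellular
Spirulina_sp_PCC6313	multicellular
Starria_zimbabweensis_SAG74.90	multicellular
Symploca_sp_PCC8002	multicellular
Trichodesmium_erythraeum_IMS101	multicellular
Anabaena_sp_PCC7108	multicellular
Calothrix_sp_PCC7103	multicellular
Nodularia_sp_PCC7804	multicellular
Nostoc_sp_PCC7120	multicellular
Scytonema_sp_U-3-3	multicellular
Chlorogloeopsis_sp_PCC7518	multicellular
Fischerella_sp_PCC7414	multicellular
Symphyonema_sp_1517	multicellular
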