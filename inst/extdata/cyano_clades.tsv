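# Partial clade membership for the deep clades E, AC and C, transcribed from
# the textual clade descriptions of the source study (figure topologies are
# not machine-readable). Intended for mrca-mode node queries, which only
# need a subset of a clade's tips. Not an exhaustive membership list.
E	Chroococcidiopsis_sp_CC2
E	Dermocarpa_sp_MBIC10768
E	Dermocarpella_incrassata
E	Myxosarcina_sp_PCC7312
E	Myxosarcina_sp_PCC7325
E	Pleurocapsa_sp_CALU1126
E	Pleurocapsa_sp_PCC7516
E	Synechocystis_sp_PCC6803
E	Synechocystis_sp_PCC6308
E	Synechocystis_sp_CR_L29
E	Microcystis_aeruginosa_038
E	Gloeothece_sp_PCC6909-1
E	Oscillatoria_sp
E	Oscillatoria_sancta_PCC7515
E	Trichodesmium_erythraeum_IMS101
E	Arthrospira_platensis_PCC8005
E	Lyngbya_aestuarii_PCC7419
E	Microcoleus_chthonoplastes_PCC7420
E	Spirulina_sp_PCC6313
E	Anabaena_sp_PCC7108
E	Calothrix_sp_PCC7103
E	Nodularia_sp_PCC7804
E	Nostoc_sp_PCC7120
E	Scytonema_sp_U-3-3
E	Chlorogloeopsis_sp_PCC7518
E	Fischerella_sp_PCC7414
E	Symphyonema_sp_1517
AC	Acaryochloris_sp_JJ8A6
AC	Synechococcus_lividus_C1
AC	Thermosynechococcus_elongatus_BP-1
AC	Synechococcus_sp_C9
AC	Filamentous_thermophilic_cyanobacterium
AC	Prochlorothrix_hollandica
AC	Prochlorococcus_sp_MIT9313
AC	Synechococcus_sp_CC9605
AC	Synechococcus_sp_WH8101
AC	Plectonema_sp_F3
C	Pseudanabaena_sp_PCC6802
C	Pseudanabaena_sp_PCC7304
C	Arthronema_gygaxiana_UTCC393
C	Phormidium_mucicola_IAM_M-221
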