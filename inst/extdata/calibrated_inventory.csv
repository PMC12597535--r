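"id","step","category","behavior","block_capacity","valuation","currency","quantity_low","quantity_base","quantity_high","unit_cost","role","annual_salary","employer_contribution_rate","social_security_rate","annual_hours","hours_low","hours_base","hours_high","allocation_weight","purchase_price","lifetime_low","lifetime_base","lifetime_high","annual_maintenance","area_m2","rate_per_m2_year","gb_low","gb_base","gb_high","price_per_gb_year","storage_years"
"c2_slides_stains",2,"consumables","variable",,"unit_price","NOK",1,1,1,223.46064,,,,,,,,,1,,,,,,,,,,,,
"c3_extraction_kit",3,"consumables","variable",,"unit_price","NOK",1,1,1,352.38024,,,,,,,,,1,,,,,,,,,,,,
"c4_libprep_reagent_kit",4,"consumables","variable",,"unit_price","USD",1,1,1,687.2,,,,,,,,,1,,,,,,,,,,,,
"c4_tube_strips",4,"consumables","step_fixed",8,"unit_price","USD",1,1,1,4.8,,,,,,,,,1,,,,,,,,,,,,
"c5_seq_reagent_kit",5,"consumables","step_fixed",24,"unit_price","USD",1,1,1,998.4,,,,,,,,,1,,,,,,,,,,,,
"c5_flowcell_consumables",5,"consumables","variable",,"unit_price","USD",1,1,1,189.8,,,,,,,,,1,,,,,,,,,,,,
"p1_request_coordination",1,"personnel","variable",,"personnel","NOK",1,1,1,,"coordinator",560000,0.13,0.25,1695,1.83342088285714,2.29177610357143,3.208486545,1,,,,,,,,,,,,
"p1_sample_request",1,"personnel","variable",,"personnel","NOK",1,1,1,,"pathologist",1300000,0.13,0.25,1695,0.396675692307692,0.495844615384615,0.694182461538462,1,,,,,,,,,,,,
"p2_sample_evaluation",2,"personnel","variable",,"personnel","NOK",1,1,1,,"pathologist",1300000,0.13,0.25,1695,0.634681107692308,0.793351384615385,1.11069193846154,1,,,,,,,,,,,,
"p2_sectioning",2,"personnel","variable",,"personnel","NOK",1,1,1,,"engineer",650000,0.13,0.25,1695,0.428409747692308,0.535512184615385,0.749717058461538,1,,,,,,,,,,,,
"p3_extraction",3,"personnel","variable",,"personnel","NOK",1,1,1,,"engineer",650000,0.13,0.25,1695,1.48674049476923,1.85842561846154,2.60179586584615,1,,,,,,,,,,,,
"p4_libprep_per_sample",4,"personnel","variable",,"personnel","NOK",1,1,1,,"engineer",650000,0.13,0.25,1695,0.963128580923077,1.20391072615385,1.68547501661538,1,,,,,,,,,,,,
"p4_libprep_per_batch",4,"personnel","step_fixed",12,"personnel","NOK",1,1,1,,"engineer",650000,0.13,0.25,1695,7.61617329230769,9.52021661538462,13.3283032615385,1,,,,,,,,,,,,
"p5_seq_run_setup",5,"personnel","step_fixed",24,"personnel","NOK",1,1,1,,"engineer",650000,0.13,0.25,1695,4.11273357784616,5.14091697230769,7.19728376123077,1,,,,,,,,,,,,
"p5_seq_monitoring",5,"personnel","variable",,"personnel","NOK",1,1,1,,"engineer",650000,0.13,0.25,1695,0.153116817230769,0.191396021538462,0.267954430153846,1,,,,,,,,,,,,
"p6_pipeline_per_run",6,"personnel","step_fixed",24,"personnel","NOK",1,1,1,,"bioinformatician",9e+05,0.13,0.25,1695,4.1254272,5.156784,7.2194976,1,,,,,,,,,,,,
"p6_qc_review",6,"personnel","variable",,"personnel","NOK",1,1,1,,"bioinformatician",9e+05,0.13,0.25,1695,0.204552432,0.25569054,0.357966756,1,,,,,,,,,,,,
"p7_variant_interpretation",7,"personnel","variable",,"personnel","NOK",1,1,1,,"molecular_biologist",850000,0.13,0.25,1695,3.54058722635294,4.42573403294118,6.19602764611765,1,,,,,,,,,,,,
"p8_mtb_molbio",8,"personnel","variable",,"personnel","NOK",1,1,1,,"molecular_biologist",850000,0.13,0.25,1695,1.45603312941176,1.82004141176471,2.54805797647059,1,,,,,,,,,,,,
"p8_mtb_oncologist",8,"personnel","variable",,"personnel","NOK",1,1,1,,"oncologist",1500000,0.13,0.25,1695,0.41254272,0.5156784,0.72194976,1,,,,,,,,,,,,
"p8_final_report",8,"personnel","variable",,"personnel","NOK",1,1,1,,"pathologist",1300000,0.13,0.25,1695,0.212618171076923,0.265772713846154,0.372081799384615,1,,,,,,,,,,,,
"e2_microtome",2,"equipment","fixed",,"equipment","NOK",,,,,,,,,,,,,1,503185.309651617,8,10,12,5000,,,,,,,
"sp2_processing_space",2,"equipment","fixed",,"space","NOK",,,,,,,,,,,,,1,,,,,,4.91613408,3000,,,,,
"e3_extraction_robot",3,"equipment","fixed",,"equipment","NOK",,,,,,,,,,,,,1,756717.34935741,5,7,9,8000,,,,,,,
"sp3_extraction_space",3,"equipment","fixed",,"space","NOK",,,,,,,,,,,,,1,,,,,,13.18417776,3000,,,,,
"e4_libprep_instruments",4,"equipment","fixed",,"equipment","NOK",,,,,,,,,,,,,1,1425433.26591752,4,5,7,15000,,,,,,,
"sp4_libprep_space",4,"equipment","fixed",,"space","NOK",,,,,,,,,,,,,1,,,,,,14.07802032,3000,,,,,
"e5_sequencer",5,"equipment","fixed",,"equipment","NOK",,,,,,,,,,,,,0.9,7909369.67658225,4,5,7,160000,,,,,,,
"sp5_sequencing_space",5,"equipment","fixed",,"space","NOK",,,,,,,,,,,,,1,,,,,,21.11703048,6000,,,,,
"e8_mtb_av_equipment",8,"equipment","fixed",,"equipment","NOK",,,,,,,,,,,,,1,26859.7908158897,4,5,7,0,,,,,,,
"s5_sequencer_software",5,"software_storage","fixed",,"unit_price","USD",1,1,1,19188,,,,,,,,,0.8,,,,,,,,,,,,
"s7_knowledgebase_license",7,"software_storage","fixed",,"unit_price","USD",1,1,1,1622.4,,,,,,,,,1,,,,,,,,,,,,
"s9_genomic_data_storage",9,"software_storage","variable",,"storage","NOK",,,,,,,,,,,,,1,,,,,,,,50,100,200,0.09346671,10
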