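"study_id","species","mean_group_size","contest_type","larger_wins"
"synthetic_study_01","synthetic_species_01",4,"resource","yes"
"synthetic_study_02","synthetic_species_02",8.6,"resource","yes"
"synthetic_study_03","synthetic_species_03",13.1,"resource","yes"
"synthetic_study_04","synthetic_species_04",17.7,"resource","yes"
"synthetic_study_05","synthetic_species_05",22.2,"resource","yes"
"synthetic_study_06","synthetic_species_06",26.8,"resource","yes"
"synthetic_study_07","synthetic_species_07",31.4,"resource","yes"
"synthetic_study_08","synthetic_species_08",35.9,"resource","yes"
"synthetic_study_09","synthetic_species_09",40.5,"resource","yes"
"synthetic_study_10","synthetic_species_10",45.1,"resource","no"
"synthetic_study_11","synthetic_species_11",49.6,"resource","no"
"synthetic_study_12","synthetic_species_12",54.2,"resource","no"
"synthetic_study_13","synthetic_species_13",58.8,"resource","no"
"synthetic_study_14","synthetic_species_14",63.3,"territorial","yes"
"synthetic_study_15","synthetic_species_15",67.9,"territorial","yes"
"synthetic_study_16","synthetic_species_16",72.4,"territorial","yes"
"synthetic_study_17","synthetic_species_17",77,"territorial","yes"
"synthetic_study_18","synthetic_species_18",81.6,"territorial","yes"
"synthetic_study_19","synthetic_species_19",86.1,"territorial","yes"
"synthetic_study_20","synthetic_species_20",90.7,"territorial","yes"
"synthetic_study_21","synthetic_species_21",95.2,"territorial","yes"
"synthetic_study_22","synthetic_species_22",99.8,"territorial","yes"
"synthetic_study_23","synthetic_species_23",104.4,"territorial","yes"
"synthetic_study_24","synthetic_species_24",108.9,"territorial","yes"
"synthetic_study_25","synthetic_species_25",113.5,"territorial","yes"
"synthetic_study_26","synthetic_species_26",118.1,"territorial","yes"
"synthetic_study_27","synthetic_species_27",122.6,"territorial","yes"
"synthetic_study_28","synthetic_species_28",127.2,"territorial","yes"
"synthetic_study_29","synthetic_species_29",131.8,"territorial","yes"
"synthetic_study_30","synthetic_species_30",136.3,"territorial","no"
"synthetic_study_31","synthetic_species_31",140.9,"territorial","no"
"synthetic_study_32","synthetic_species_32",145.4,"territorial","no"
"synthetic_study_33","synthetic_species_33",150,"territorial","no"
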