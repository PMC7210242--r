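row_id,printed_histology,histology,distance_class,distance_mm,on_ink,device_reading,tumor_found_additional,additional_histology,excised_intraoperatively
1,DCIS < 2 mm from ink,DCIS,lt_2mm,1,FALSE,positive,TRUE,DCIS,TRUE
2,DCIS < 2 mm from ink,DCIS,lt_2mm,1,FALSE,positive,FALSE,benign,TRUE
3,DCIS < 2 mm from ink,DCIS,lt_2mm,1,FALSE,positive,TRUE,DCIS,FALSE
4,IDC on ink,IDC,on_ink,0,TRUE,positive,TRUE,IDC,FALSE
5,ILC on ink,ILC,on_ink,0,TRUE,positive,TRUE,ILC,FALSE
6,DCIS < 2 mm from ink,DCIS,lt_2mm,1,FALSE,positive,FALSE,benign,FALSE
7,IDC on ink,IDC,on_ink,0,TRUE,negative,FALSE,benign,FALSE
8,DCIS < 2 mm from ink,DCIS,lt_2mm,1,FALSE,negative,FALSE,benign,FALSE
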