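row_id,printed_histology,histology,distance_class,distance_mm,on_ink,device_reading
1,IC on ink,IC_mixed,on_ink,0,TRUE,positive
2,IDC on ink,IDC,on_ink,0,TRUE,positive
3,IDC < 1 mm from ink,IDC,lt_1mm,0.5,FALSE,positive
4,"IDC < 1 mm from ink, DCIS on ink",IDC_DCIS,on_ink,0,TRUE,positive
5,IDC > 2 mm from ink,IDC,gt_2mm,3,FALSE,positive
6,IDC > 2 mm from ink,IDC,gt_2mm,3,FALSE,negative
7,DCIS < 2 mm from ink,DCIS,lt_2mm,1,FALSE,positive
8,DCIS < 2 mm from ink,DCIS,lt_2mm,1,FALSE,negative
9,DCIS > 2 mm from ink,DCIS,gt_2mm,3,FALSE,negative
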