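analyte_id,name,class,method,polarity,precursor_mz,product_mz,role,rt_min,window_s,calib_set,flags
ala,alanine,amino acids,HILIC,positive,90.1,44.1,quantifier,7.9,30,HILIC,report_as_sum
ala,alanine,amino acids,HILIC,positive,90.1,72.1,qualifier,7.9,30,HILIC,report_as_sum
val,valine,amino acids,HILIC,positive,118.1,72.1,quantifier,7.2,30,HILIC,
val,valine,amino acids,HILIC,positive,118.1,55.1,qualifier,7.2,30,HILIC,
ile,isoleucine,amino acids,HILIC,positive,132.1,69.0,quantifier,6.9,30,HILIC,
ile,isoleucine,amino acids,HILIC,positive,132.1,86.1,qualifier,6.9,30,HILIC,
leu_ile_sum,leucine+isoleucine,amino acids,HILIC,positive,132.1,89.0,quantifier,6.9,30,HILIC,single_transition;report_as_sum;unique_partner:ile
met,methionine,amino acids,HILIC,positive,150.1,104.1,quantifier,6.8,30,HILIC,
met,methionine,amino acids,HILIC,positive,150.1,56.1,qualifier,6.8,30,HILIC,
ser,serine,amino acids,HILIC,positive,106.0,60.0,quantifier,8.1,30,HILIC,both_polarity
ser,serine,amino acids,HILIC,negative,104.0,74.0,qualifier,8.1,30,HILIC,both_polarity
thr,threonine,amino acids,HILIC,positive,120.1,74.1,quantifier,7.8,30,HILIC,
thr,threonine,amino acids,HILIC,positive,120.1,56.1,qualifier,7.8,30,HILIC,
crea,creatinine,amino acid related,HILIC,positive,114.1,44.1,quantifier,5.3,30,HILIC,
crea,creatinine,amino acid related,HILIC,positive,114.1,86.1,qualifier,5.3,30,HILIC,
tmao,trimethylamine-N-oxide,biogenic amines,HILIC,positive,76.1,58.1,quantifier,8.4,30,HILIC,
tmao,trimethylamine-N-oxide,biogenic amines,HILIC,positive,76.1,59.1,qualifier,8.4,30,HILIC,
carn,carnitine,carnitines,HILIC,positive,162.1,103.1,quantifier,9.2,30,HILIC,
carn,carnitine,carnitines,HILIC,positive,162.1,60.1,qualifier,9.2,30,HILIC,
urea,urea,amino acid related,HILIC,positive,61.1,44.1,quantifier,3.9,30,HILIC,
urea,urea,amino acid related,HILIC,positive,61.1,43.1,qualifier,3.9,30,HILIC,
hipp,hippuric acid,carboxylic acids,RP,negative,178.1,134.1,quantifier,3.4,30,RP_Aqu,
hipp,hippuric acid,carboxylic acids,RP,negative,178.1,77.0,qualifier,3.4,30,RP_Aqu,
indox,3-indoxylsulfate,carboxylic acids,RP,negative,212.0,80.0,quantifier,3.1,30,RP_Aqu,
indox,3-indoxylsulfate,carboxylic acids,RP,negative,212.0,132.1,qualifier,3.1,30,RP_Aqu,
gca,glycocholic acid,bile acids,RP,positive,466.3,404.3,quantifier,5.8,30,RP_Aqu,both_polarity
gca,glycocholic acid,bile acids,RP,negative,464.3,74.0,qualifier,5.8,30,RP_Aqu,both_polarity
cdca,chenodeoxycholic acid,bile acids,RP,negative,391.3,391.3,quantifier,7.2,30,RP_Aqu,
cdca,chenodeoxycholic acid,bile acids,RP,negative,391.3,373.3,qualifier,7.2,30,RP_Aqu,
lpc16,1-palmitoyl-2-hydroxy-sn-glycero-3-phosphatidylcholine,phospholipids,RP,positive,496.3,184.1,quantifier,8.9,30,RP_Hep,
lpc16,1-palmitoyl-2-hydroxy-sn-glycero-3-phosphatidylcholine,phospholipids,RP,positive,496.3,104.1,qualifier,8.9,30,RP_Hep,
pc3434,1-stearoyl-2-arachidonoyl-sn-glycero-3-phosphatidylcholine,phospholipids,RP,positive,810.6,184.1,quantifier,12.4,60,RP_Hep,
pc3434,1-stearoyl-2-arachidonoyl-sn-glycero-3-phosphatidylcholine,phospholipids,RP,positive,810.6,104.1,qualifier,12.4,60,RP_Hep,
sm16,C16 sphingomyelin,phospholipids,RP,positive,703.6,184.1,quantifier,11.8,60,RP_Hep,
sm16,C16 sphingomyelin,phospholipids,RP,positive,703.6,86.1,qualifier,11.8,60,RP_Hep,
chol,cholesterol,sterols,RP,positive,369.4,161.1,quantifier,10.2,30,RP_Hep,
chol,cholesterol,sterols,RP,positive,369.4,95.1,qualifier,10.2,30,RP_Hep,
chms,cholesteryl myristate,cholesterol esters,RP,positive,614.6,369.4,quantifier,14.1,30,RP_Hep,single_transition
olea,oleic acid,fatty acids,RP,negative,281.2,281.2,quantifier,9.6,30,RP_Hep,
olea,oleic acid,fatty acids,RP,negative,281.2,263.2,qualifier,9.6,30,RP_Hep,
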