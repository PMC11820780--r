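compound,certified_ugL,measured_ugL
Methionine,3325,2146
Leucine,13158,9038
Proline,20298,15859
Valine,21318,17053
Threonine,14219,11915
Alanine,26724,22449
Serine,10067,9218
Isoleucine,7273,6823
Tyrosine,10373,9770
Phenylalanine,8364,8287
Lysine,20400,23637
Arginine,14168,23863
Creatinine,6789,7672
Urea,234500,224888
Cholesterol,1514000,645655
Cholecalciferol,25,NA
Calciferol,1.0,NA
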