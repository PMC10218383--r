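case_id,physical_sex,physical_ancestry,molecular_sex,str_call,y_call,mt_call,known_sex,known_provenance,y_haplogroup,mt_haplogroup
Evidence 1,M,European,M,Eur_Am,EU,EU,M,Italy,R1b M269,H1
Evidence 2,M,European,M,Afr_Am,EU,EU,M,Italy,R1b M269,U5a1b1g
Evidence 3,M,European,M,Eur_Am,EU,EU,,,R1b M269,R0
Evidence 4,M,European,M,Eur_Am,EU,EU,,,I2a1b3,H
Evidence 5,M,European,M,NA,ND,EU,,,,U6a3b
Evidence 6,F,European,F,Eur_Am,NA,AS,F,Ukraine,,M5a1b
Evidence 7,F,African,F,Afr_Am,NA,AF,F,Nigeria,,L2a1a1
Evidence 8,M,European,M,Eur_Am,NA,EU,M,Germany,,U4b1a3a
Evidence 9,M,European,M,Eur_Am,EU,EU,M,Italy,J2a1 M67,T2e2a
Evidence 10,IND,European,F,Eur_Am,NA,ND,,,,L3e1a3a
Evidence 12,M,European,M,Eur_Am,EU,AF,M,Morocco,E1b1b L67,L2a1c1
Evidence 14,F,European,F,Eur_Am,NA,AS,,,,M5a1b
Evidence 15,F,European,F,ND,NA,ND,,,,M1a1
Evidence 16,M,European,M,Eur_Am,EU,EU,,,I2a1b3,T1a10
Evidence 17,M,European,ND,NA,NA,EU,,,,H1bp
Evidence 18,F,European,F,Eur_Am,NA,EU,,,,K1a
Evidence 19,F,European,ND,NA,NA,EU,,,,T2+16189
Evidence 20,F,European,F,Eur_Am,NA,EU,,,,H41a
Evidence 21,M,European,M,Eur_Am,EU,EU,,,E1b1b >V13,H1b1+16362
Evidence 22,F,African,F,Asian,NA,EU,,,,R9c1b1
Evidence 23,F,African,F,Afr_Am,NA,AF,,,,L2b1b
Evidence 24,M,European,M,Eur_Am,EU,EU,,,E1b1b >V13,U5a1c
Evidence 25,F,European,F,Eur_Am,NA,EU,F,Italy,,J2b1c
Evidence 26,M,European,M,Eur_Am,EU,EU,M,Italy,R1b,K1a4a1h
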