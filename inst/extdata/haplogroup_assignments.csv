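case_id,y_label,y_region,mt_label,mt_subclade,continent
Evidence 1,R1b M269,western Europe,H1,H1,Europe
Evidence 2,R1b M269,western Europe,U5a,U5a1b1g,Europe
Evidence 3,R1b M269,western Europe,R0,R0,South Asian
Evidence 4,I2a1b3,"south-eastern, south-western, north-western Europe",H,H,Europe
Evidence 5,,,U6a,U6a3b,Europe
Evidence 6,,,M5a,M5a1b,South Asia
Evidence 7,,,L2a,L2a1a1,Africa/Africa America
Evidence 8,,,U4b,U4b1a3a,Europe
Evidence 9,J2a1 M67,"Europe, the Middle East and northern Africa",T2e,T2e2a,Europe
Evidence 10,,,L3e,L3e1a3a,Africa/Africa America
Evidence 12,E1b1b L67,"Europe, the Near East, and northern Africa",L2a,L2a1c1,Africa/Africa America
Evidence 14,,,M5a,M5a1b,South Asia
Evidence 15,,,M1a,M1a1,South Asia
Evidence 16,I2a1b3,"south-eastern, south-western, north-western Europe",T1a,T1a10,Europe
Evidence 17,,,H1b,H1bp,Europe
Evidence 18,,,K1a,K1a,Europe
Evidence 19,,,T2,T2+16189,Europe
Evidence 20,,,H41a,H41a,Europe
Evidence 21,E1b1b >V13,"Europe, the Near East, and northern Africa",H1b,H1b1+16362,Europe
Evidence 22,,,R9c,R9c1b1,South Asia
Evidence 23,,,L2b,L2b1b,Africa/Africa America
Evidence 24,E1b1b >V13,"Europe, the Near East, and northern Africa",U5a,U5a1c,Europe
Evidence 25,,,J2b,J2b1c,Europe
Evidence 26,R1b,western Europe,K1a,K1a4a1h,Europe
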