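icer_rank,id,name,icer_usd,cost_saving,dalys_per_1000,cases_1000s,cost_full_1000s,dalys_full_1000s,implementation_pct,net_dalys_full_1000s,net_dalys_actual_1000s,scaleup_value_1000s,low_confidence
1,i01,"Cotrimoxazole for children",NA,1,NA,127,220,0,13,23,3,1208,1
2,i02,"Mass media",1,0,903,16879,7609,150,71,148,105,2627,0
3,i03,"Isoniazid preventive therapy for children in contact with patients with TB",1,0,900,2,7,45,85,44,38,408,0
4,i04,"Isoniazid preventive therapy for HIV+ no TB",1,0,887,55,80,1118,50,1098,549,33673,0
5,i05,"First-line treatment for new TB cases for adults",3,0,393,14,178,1045,64,1002,641,22122,0
6,i06,"First-line treatment for retreatment TB cases for adults",3,0,393,2,100,131,65,125,81,2688,0
7,i07,"First-line treatment for new TB cases for children",3,0,393,12,117,888,64,851,545,18789,0
8,i08,"First-line treatment for retreatment TB cases for children",3,0,393,2,66,111,65,106,69,2283,0
9,i09,"Clean practices and immediate essential newborn care (home)",3,0,368,671,416,237,0,227,NA,13909,0
10,i10,"Case management of MDR TB cases",3,0,297,0,12,5,100,5,5,0,0
11,i11,"Malaria treatment: uncomplicated (adult, <36 kg)",4,0,260,4372,3463,59,30,56,17,2383,0
12,i12,"Malaria treatment: uncomplicated (adult, >36 kg)",4,0,260,4372,4267,59,70,56,39,1021,0
13,i13,"Malaria treatment: uncomplicated, second line (adult, >36 kg)",4,0,260,4372,1186,59,2,56,1,3354,0
14,i14,"Malaria treatment: uncomplicated, second line (adult, <36 kg)",4,0,260,4372,593,59,4,56,2,3285,0
15,i15,"Malaria treatment: uncomplicated (children, <15 kg)",4,0,260,1042,4576,14,60,13,8,325,0
16,i16,"Malaria treatment: uncomplicated (children, >15 kg)",4,0,260,1042,4768,14,40,13,5,487,0
17,i17,"Malaria treatment: uncomplicated, second line (children, <15 kg)",4,0,260,1042,35,14,2,13,0,799,0
18,i18,"Malaria treatment: uncomplicated, second line (children, >15 kg)",4,0,260,1042,71,14,4,13,0,783,0
19,i19,"Malaria treatment: first trimester, uncomplicated",5,0,198,305,1025,109,33,100,33,4087,0
20,i20,"Malaria treatment: second trimester, uncomplicated",5,0,198,305,235,109,67,100,67,2047,0
21,i21,"Malaria treatment: pregnant women, complicated",5,0,198,16,140,6,100,5,5,0,0
22,i22,"Rotavirus vaccine",6,0,177,651,3097,88,0,80,NA,4920,0
23,i23,"Management of pre-eclampsia (magnesium sulfate)",6,0,168,20,45,535,80,483,386,5923,0
24,i24,"Tetanus toxoid (pregnant women)",7,0,149,918,115,104,84,92,77,905,0
25,i25,"Vitamin A supplementation in pregnant women",7,0,140,124,125,33,65,30,19,634,0
26,i26,"Measles vaccine",9,0,106,651,528,107,99,90,89,55,0
27,i27,"PMTCT of HIV",11,0,94,53,600,157,55,130,72,3561,0
28,i28,"Labour and delivery management",11,0,89,918,1281,170,65,139,91,2992,0
29,i29,"Caesarean section (with complication)",12,0,86,5,172,137,100,111,111,0,0
30,i30,"Management of obstructed labour",12,0,86,92,1100,2497,100,2026,2026,0,0
31,i31,"Vaginal delivery, skilled attendance",12,0,83,918,5181,67,65,54,35,1153,0
32,i32,"Vaginal delivery, with complication",12,0,83,138,804,10,51,8,4,242,0
33,i33,"Households owning at least one ITN/LLIN",13,0,77,6752,13737,228,56,180,101,4847,0
34,i34,"Pregnant women sleeping under an ITN",13,0,77,1469,2990,50,100,39,39,0,0
35,i35,"Under five children who slept under ITN/LLIN",13,0,77,494,1006,17,100,13,13,0,0
36,i36,"Antenatal care (four visits)",15,0,68,918,11230,90,46,68,31,2289,0
37,i37,"Blood safety",15,0,66,40,1626,12,100,9,9,0,0
38,i38,"Male circumcision",22,0,45,4073,146730,39634,12,25423,3051,1372314,0
39,i39,"Newborn sepsis, full supportive care",24,0,42,81,417,60,40,37,15,1346,0
40,i40,"Antenatal corticosteroids for preterm labour",25,0,40,165,406,47,0,28,NA,1718,0
41,i41,"Voluntary counselling and testing",25,0,40,8031,36309,167,15,98,15,5120,0
42,i42,"Schistosomiasis mass drug administration",29,0,35,389,77,24,13,13,2,670,0
43,i43,"Caesarean section",32,0,31,34,672,327,100,157,157,0,0
44,i44,"Maternal sepsis case management",39,0,26,64,2731,20,0,7,NA,449,0
45,i45,"Antibiotics for pPRoM",40,0,25,64,39,30,30,10,3,450,0
46,i46,"Management of severe malnutrition (children)",50,0,20,51,2437,199,80,36,29,446,0
47,i47,"Interventions focused on female sex workers",51,0,20,23,655,161,30,28,8,1184,0
48,i48,"Interventions focused on men who have sex with men",51,0,20,34,1256,232,5,40,2,2311,0
49,i49,"High cholesterol",68,0,15,223,6703,1,1,0,0,-6,0
50,i50,"Basic psychosocial support, advice and follow-up, plus antiepileptic medication",82,0,12,506,1266,1,3,0,0,-14,0
51,i51,"Zinc (diarrhoea treatment)",99,0,10,7455,1788,244,0,-150,NA,-9207,0
52,i52,"IPT of malaria (pregnant women)",110,0,9,735,35,0,100,0,0,0,0
53,i53,"Condoms",127,0,8,8031,22883,482,47,-517,-243,-16813,0
54,i54,"ORS",153,0,7,8662,937,147,69,-221,-152,-4197,0
55,i55,"Hypertension",159,0,6,846,1338,44,10,-71,-7,-3912,0
56,i56,"Treatment of depression",265,0,4,169,332,0,1,0,0,-23,0
57,i57,"Diabetes, type I",296,0,3,23,4304,0,15,0,0,-5,0
58,i58,"Diabetes, type II",296,0,3,138,4211,0,15,-1,0,-30,0
59,i59,"ART for men",312,0,3,332,21159,1005,75,-4104,-3096,-61848,0
60,i60,"ART for women",312,0,3,509,32440,1541,82,-6292,-5173,-68665,0
61,i61,"Ischaemic heart disease",453,0,2,128,4,0,15,0,0,-2,0
62,i62,"Treatment of bipolar disorder",557,0,2,523,10362,0,3,-1,0,-87,0
63,i63,"GIT tract cancer",804,0,1,0,3,0,50,0,0,0,0
64,i64,"Paediatric ART",892,0,1,107,7657,1556,25,-21074,-5206,-973334,0
65,i65,"Cervical cancer (first line)",1087,0,1,2,162,0,50,0,0,0,0
66,i66,"Treatment of acute psychotic disorders",1646,0,1,169,958,0,1,-1,0,-42,0
67,i67,"Treatment of schizophrenia",1646,0,1,2363,13413,0,14,-10,-1,-512,0
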