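study_id,treatment_a,treatment_b,n_a,n_b,endpoint,measure,estimate,ci_lower,ci_upper
Baselga-2013,Cetuximab + CT,CT,115,58,OS,HR,0.82,0.56,1.20
Bell-2016,Bevacizumab + CT,CT,1301,1290,OS,HR,0.93,0.74,1.17
Brufsky-2012,Bevacizumab + CT,CT + Placebo,112,47,OS,HR,0.62,0.39,1.01
Carey-2012,Cetuximab + CT,Cetuximab,71,31,OS,HR,0.93,0.57,1.50
Curigliano-2013,Sunitinib,CT,113,104,OS,HR,1.16,0.86,1.56
Nahleh-2016,Bevacizumab + CT,CT,32,35,OS,HR,0.49,0.19,1.29
O'Shaughnessy-2011,Iniparib + CT,CT,61,62,OS,HR,0.57,0.36,0.90
O'Shaughnessy-2014,Iniparib + CT,CT,261,258,OS,HR,0.85,0.69,1.04
Yardley-2015,Glembatumumab vedotin,CT,28,11,OS,HR,0.65,0.29,1.45
Baselga-2012,Sorafenib + CT,CT + Placebo,20,33,PFS,HR,0.60,0.31,1.14
Baselga-2013,Cetuximab + CT,CT,115,58,PFS,HR,0.67,0.47,0.97
Bergh-2012,Sunitinib + CT,CT,58,69,PFS,HR,1.03,0.65,1.63
Brufsky-2012,Bevacizumab + CT,CT + Placebo,112,47,PFS,HR,0.49,0.33,0.74
Carey-2012,Cetuximab + CT,Cetuximab,71,31,PFS,HR,0.49,0.23,0.64
Curigliano-2013,Sunitinib,CT,113,104,PFS,HR,1.20,0.89,1.63
Finn-2009,Lapatinib + CT,CT + Placebo,71,60,PFS,HR,1.25,0.85,1.83
Forero-2015,Tigatuzumab + CT,CT,39,21,PFS,HR,1.27,0.76,2.19
Gray-2009,Bevacizumab + CT,CT,232,NA,PFS,HR,0.49,0.34,0.70
Han-2018,Veliparib + CT,CT + Placebo,40,42,PFS,HR,0.82,0.47,1.40
Kim-2017,Ipatasertib + CT,CT + Placebo,62,62,PFS,HR,0.60,0.37,0.98
Kummar-2016,Veliparib + CT,CT,21,18,PFS,HR,0.57,0.21,0.81
Nahleh-2016,Bevacizumab + CT,CT,32,35,PFS,HR,0.46,0.20,1.05
O'Shaughnessy-2011,Iniparib + CT,CT,61,62,PFS,HR,0.59,0.39,0.90
O'Shaughnessy-2014,Iniparib + CT,CT,261,258,PFS,HR,0.79,0.65,0.98
Pivot-2011,Bevacizumab + CT,CT + Placebo,60,43,PFS,HR,0.68,0.46,1.00
Robert (Cape)-2011,Bevacizumab + CT,CT + Placebo,87,50,PFS,HR,0.72,0.49,1.06
Robert (Tax/Anthra)-2011,Bevacizumab + CT,CT + Placebo,96,46,PFS,HR,0.78,0.53,1.15
Robson-2017,Olaparib,CT,102,48,PFS,HR,0.43,0.29,0.63
Yardley-2015,Glembatumumab vedotin,CT,28,11,PFS,HR,0.69,0.32,1.54
Yardley-2016,Ramucirumab + CT,CT,21,22,PFS,HR,0.66,0.32,1.35
Baselga-2013,Cetuximab + CT,CT,115,58,ORR,RR,1.93,0.83,4.48
Brufsky-2012,Bevacizumab + CT,CT + Placebo,112,47,ORR,RR,2.14,1.14,4.02
Carey-2012,Cetuximab + CT,Cetuximab,71,31,ORR,RR,2.62,0.62,11.02
Curigliano-2013,Sunitinib,CT,113,104,ORR,RR,0.39,0.10,1.49
Forero-2015,Tigatuzumab + CT,CT,39,21,ORR,RR,0.74,0.35,1.55
Gonzalez-2014,Everolimus + CT,CT,23,27,ORR,RR,0.76,0.50,1.16
Jovanovic-2017,Everolimus + CT,CT + Placebo,96,49,ORR,RR,0.89,0.77,1.04
Kim-2017,Ipatasertib + CT,CT + Placebo,62,62,ORR,RR,1.25,0.78,2.00
Kummar-2016,Veliparib + CT,CT,21,18,ORR,RR,1.71,0.17,17.38
Llombart-2015,Iniparib + CT,CT,94,47,ORR,RR,1.04,0.78,1.38
O'Shaughnessy-2011,Iniparib + CT,CT,61,62,ORR,RR,1.63,1.06,2.51
O'Shaughnessy-2014,Iniparib + CT,CT,261,258,ORR,RR,1.12,0.87,1.43
Robson-2017,Olaparib,CT,102,48,ORR,RR,2.58,1.30,5.11
Tredan-2015,Cetuximab + CT,CT,39,40,ORR,RR,1.20,0.64,2.25
Yardley-2015,Glembatumumab vedotin,CT,28,11,ORR,RR,4.55,0.27,76.05
Gonzalez-2014,Everolimus + CT,CT,23,27,PCR_BREAST_AXILLA,RR,1.17,0.48,2.85
Jovanovic-2017,Everolimus + CT,CT + Placebo,96,49,PCR_BREAST_AXILLA,RR,0.74,0.50,1.10
Llombart-2015,Iniparib + CT,CT,94,47,PCR_BREAST_AXILLA,RR,0.85,0.42,1.71
Minckwitz-2012,Bevacizumab + CT,CT,323,340,PCR_BREAST_AXILLA,RR,1.32,1.08,1.60
Nahleh-2016,Bevacizumab + CT,CT,32,35,PCR_BREAST_AXILLA,RR,2.08,1.14,3.78
Sikov (No carbo)-2015,Bevacizumab + CT,CT,105,107,PCR_BREAST_AXILLA,RR,1.02,0.74,1.40
Sikov (With carbo)-2015,Bevacizumab + CT,CT,110,111,PCR_BREAST_AXILLA,RR,1.34,1.05,1.71
Llombart-2015,Iniparib + CT,CT,94,47,PCR_BREAST,RR,0.95,0.48,1.88
Minckwitz-2012,Bevacizumab + CT,CT,323,340,PCR_BREAST,RR,1.28,1.07,1.54
Sikov (No carbo)-2015,Bevacizumab + CT,CT,105,107,PCR_BREAST,RR,1.20,0.90,1.61
Sikov (With carbo)-2015,Bevacizumab + CT,CT,110,111,PCR_BREAST,RR,1.27,1.02,1.57
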