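rank,drug,a,ror,ror_lo,ror_hi,ror_star,prr,chi2,prr_star,ebgm,eb05,mgps_star,ic,ic025,ic_star
1,SEVELAMER CARBONATE,2369,115.51,110.14,121.15,TRUE,83.78,191709.73,TRUE,82.63,79.4,TRUE,6.37,4.70,TRUE
2,PATIROMER,2100,24.90,23.81,26.04,TRUE,23.07,43942.56,TRUE,22.8,21.96,TRUE,4.51,2.84,TRUE
3,SOLIFENACIN SUCCINATE,1135,14.76,13.91,15.67,TRUE,14.12,13787.01,TRUE,14.03,13.34,TRUE,3.81,2.14,TRUE
4,ORLISTAT,1918,11.46,10.94,11.99,TRUE,11.07,17433.80,TRUE,10.96,10.55,TRUE,3.45,1.79,TRUE
5,ERENUMAB,2966,9.65,9.30,10.01,TRUE,9.38,21897.46,TRUE,9.24,8.96,TRUE,3.21,1.54,TRUE
6,NIRAPARIB,3651,9.14,8.84,9.45,TRUE,8.90,25133.71,TRUE,8.73,8.49,TRUE,3.13,1.46,TRUE
7,SEMAGLUTIDE,1214,5.81,5.49,6.15,TRUE,5.72,4707.24,TRUE,5.68,5.42,TRUE,2.51,0.84,TRUE
8,NINTEDANIB,1177,4.56,4.31,4.83,TRUE,4.51,3201.12,TRUE,4.48,4.27,TRUE,2.16,0.50,TRUE
9,CABOZANTINIB,1260,4.06,3.84,4.29,TRUE,4.02,2846.02,TRUE,4,3.81,TRUE,2.00,0.33,TRUE
10,LENALIDOMIDE,7730,3.81,3.72,3.90,TRUE,3.78,15109.69,TRUE,3.65,3.58,TRUE,1.87,0.20,TRUE
11,POMALIDOMIDE,1628,3.71,3.53,3.89,TRUE,3.67,3149.79,TRUE,3.65,3.5,TRUE,1.87,0.20,TRUE
12,ENZALUTAMIDE,1368,3.19,3.02,3.36,TRUE,3.16,2016.09,TRUE,3.15,3.01,TRUE,1.65,-0.01,FALSE
13,VARENICLINE,2059,2.85,2.73,2.98,TRUE,2.84,2427.64,TRUE,2.81,2.71,TRUE,1.49,-0.17,FALSE
14,PALBOCICLIB,2127,2.82,2.70,2.95,TRUE,2.81,2448.58,TRUE,2.78,2.68,TRUE,1.48,-0.19,FALSE
15,DULAGLUTIDE,1066,2.36,2.22,2.50,TRUE,2.34,819.90,TRUE,2.34,2.22,TRUE,1.22,-0.44,FALSE
16,TERIPARATIDE,2300,2.00,1.92,2.09,TRUE,1.99,1130.24,FALSE,1.98,1.91,FALSE,0.99,-0.68,FALSE
17,DALFAMPRIDINE,1099,1.93,1.82,2.05,TRUE,1.92,484.70,FALSE,1.92,1.82,FALSE,0.94,-0.73,FALSE
18,CAPECITABINE,963,1.90,1.78,2.03,TRUE,1.90,406.31,FALSE,1.89,1.79,FALSE,0.92,-0.75,FALSE
19,CLOZAPINE,1227,1.71,1.61,1.81,TRUE,1.70,354.65,FALSE,1.70,1.62,FALSE,0.76,-0.90,FALSE
20,VEDOLIZUMAB,922,1.66,1.56,1.78,TRUE,1.66,241.48,FALSE,1.66,1.57,FALSE,0.73,-0.94,FALSE
21,EXENATIDE,1294,1.57,1.49,1.66,TRUE,1.57,264.54,FALSE,1.56,1.49,FALSE,0.64,-1.02,FALSE
22,DIMETHYL FUMARATE,1517,1.54,1.46,1.62,TRUE,1.54,281.35,FALSE,1.53,1.47,FALSE,0.61,-1.05,FALSE
23,BEVACIZUMAB,904,1.51,1.41,1.61,TRUE,1.50,152.30,FALSE,1.50,1.42,FALSE,0.59,-1.08,FALSE
24,DULOXETINE HYDROCHLORIDE,963,1.28,1.20,1.36,TRUE,1.27,56.59,FALSE,1.27,1.21,FALSE,0.35,-1.32,FALSE
25,ALENDRONATE SODIUM,1135,1.23,1.16,1.31,TRUE,1.23,49.71,FALSE,1.23,1.17,FALSE,0.30,-1.37,FALSE
26,OXYCODONE,1537,1.07,1.02,1.13,TRUE,1.07,7.06,FALSE,1.07,1.03,FALSE,0.10,-1.57,FALSE
27,PREGABALIN,1054,0.87,0.82,0.92,FALSE,0.87,20.58,FALSE,0.87,0.83,FALSE,-0.20,-1.87,FALSE
28,ADALIMUMAB,3720,0.62,0.60,0.64,FALSE,0.63,821.40,FALSE,0.63,0.62,FALSE,-0.66,-2.33,FALSE
29,INFLIXIMAB,905,0.52,0.48,0.55,FALSE,0.52,407.56,FALSE,0.52,0.49,FALSE,-0.94,-2.61,FALSE
30,ETANERCEPT,1007,0.22,0.21,0.23,FALSE,0.22,2755.52,FALSE,0.23,0.21,FALSE,-2.15,-3.81,FALSE
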