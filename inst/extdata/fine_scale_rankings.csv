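study_area,rank,model,K,aicc,delta_aicc,weight,log_l
WS,1,"psi(.), p(PumaCount+HD+G+P3+G*P3)",7,1426.06,0.00,0.52,1412.06
WS,2,"psi(.), p(PumaCount+HD+G+P2+G*P2)",7,1426.98,0.92,0.33,1412.98
WS,3,"psi(.), p(PumaCount+HD+G+P4+G*P4)",7,1430.27,4.21,0.06,1416.27
WS,4,"psi(.), p(G+P3+G*P3)",5,1432.36,6.30,0.02,1422.36
WS,5,"psi(.), p(PumaCount+HD+G+P1+G*P1)",7,1433.21,7.15,0.01,1419.21
WS,6,"psi(.), p(PumaCount+HD)",4,1433.32,7.26,0.01,1425.32
WS,7,"psi(.), p(G+P2+G*P2)",5,1433.84,7.78,0.01,1423.84
WS,8,"psi(.), p(PumaCount+HD+P2)",5,1434.61,8.55,0.01,1424.61
WS,9,"psi(.), p(PumaCount+HD+P4)",5,1434.68,8.62,0.01,1424.68
WS,10,"psi(.), p(PumaCount+HD+P1)",5,1435.26,9.20,0.01,1425.26
WS,11,"psi(.), p(PumaCount+HD+P3)",5,1435.28,9.22,0.01,1425.28
WS,12,"psi(.), p(HD)",3,1435.60,9.54,0.00,1429.60
WS,13,"psi(.), p(G+P4+G*P4)",5,1437.08,11.02,0.00,1427.08
WS,14,"psi(.), p(PumaCount)",3,1438.72,12.66,0.00,1432.72
WS,15,"psi(.), p(.)",2,1439.11,13.05,0.00,1435.11
WS,16,"psi(.), p(G)",3,1439.55,13.49,0.00,1433.55
WS,17,"psi(.), p(G+P1+G*P1)",5,1439.79,13.73,0.00,1429.79
WS,18,"psi(.), p(P2)",3,1440.90,14.84,0.00,1434.90
WS,19,"psi(.), p(P4)",3,1441.03,14.97,0.00,1435.03
WS,20,"psi(.), p(P3)",3,1441.06,15.00,0.00,1435.06
WS,21,"psi(.), p(P1)",3,1441.11,15.05,0.00,1435.11
FR,1,"psi(.), p(PumaCount+HD+G+P2+G*P2)",7,1176.81,0.00,0.45,1162.81
FR,2,"psi(.), p(PumaCount+HD+G+P3+G*P3)",7,1179.01,2.20,0.15,1165.01
FR,3,"psi(.), p(PumaCount+HD+G+P1+G*P1)",7,1179.15,2.34,0.14,1165.15
FR,4,"psi(.), p(G+P2+G*P2)",5,1181.16,4.35,0.05,1171.16
FR,5,"psi(.), p(PumaCount+HD)",4,1182.27,5.46,0.03,1174.27
FR,6,"psi(.), p(PumaCount+HD+G+P4+G*P4)",7,1182.89,6.08,0.02,1168.89
FR,7,"psi(.), p(PumaCount+HD+P2)",5,1183.18,6.37,0.02,1173.18
FR,8,"psi(.), p(G+P3+G*P3)",5,1183.31,6.50,0.02,1173.31
FR,9,"psi(.), p(PumaCount+HD+P3)",5,1183.37,6.56,0.02,1173.37
FR,10,"psi(.), p(PumaCount)",3,1183.91,7.10,0.01,1177.91
FR,11,"psi(.), p(G+P1+G*P1)",5,1184.01,7.20,0.01,1174.01
FR,12,"psi(.), p(HD)",3,1184.03,7.22,0.01,1178.03
FR,13,"psi(.), p(.)",2,1184.20,7.39,0.01,1180.20
FR,14,"psi(.), p(PumaCount+HD+P4)",5,1184.21,7.40,0.01,1174.21
FR,15,"psi(.), p(PumaCount+HD+P1)",5,1184.27,7.46,0.01,1174.27
FR,16,"psi(.), p(P2)",3,1184.62,7.81,0.01,1178.62
FR,17,"psi(.), p(P3)",3,1184.76,7.95,0.01,1178.76
FR,18,"psi(.), p(G)",3,1185.46,8.65,0.01,1179.46
FR,19,"psi(.), p(P4)",3,1185.91,9.10,0.00,1179.91
FR,20,"psi(.), p(P1)",3,1186.16,9.35,0.00,1180.16
FR,21,"psi(.), p(G+P4+G*P4)",5,1187.54,10.73,0.00,1177.54
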