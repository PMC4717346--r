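study_area,rank,model,K,aicc,delta_aicc,weight,log_l
WS,1,"psiA, (psiBA=psiBa), pA, rA, (pB=rBA=rBa(G+HD))",7,480.67,0.00,0.45,466.67
WS,2,"psiA, psiBA, psiBa, pA, rA, (pB=rBA=rBa(G+HD))",8,481.66,0.99,0.27,465.66
WS,3,"psiA, (psiBA=psiBa), pA, rA, (pB=rBA=rBa(G))",6,484.37,3.70,0.07,472.37
WS,4,"psiA, (psiBA=psiBa), pA, rA, (pB=rBA=rBa(HD))",6,484.49,3.82,0.07,472.49
WS,5,"psiA, psiBA, psiBa, pA, rA, (pB=rBA=rBa(HD))",7,484.77,4.10,0.06,470.77
WS,6,"psiA, psiBA, psiBa, pA, rA, (pB=rBA=rBa(G))",7,485.59,4.92,0.04,471.59
WS,7,"psiA, (psiBA=psiBa), pA, rA, pB(G+HD), (rBA=rBa(G+HD))",10,485.62,4.95,0.04,465.62
WS,8,"psiA, psiBA, psiBa, pA, rA, pB(G+HD), (rBA=rBa(G+HD))",11,486.87,6.20,0.02,464.87
WS,9,"psiA, (psiBA=psiBa), pA, rA, (pB=rBA=rBa)",5,487.10,6.43,0.02,477.10
WS,10,"psiA, psiBA, psiBa, pA, rA, (pB=rBA=rBa)",6,487.53,6.86,0.01,475.53
WS,11,"psiA, (psiBA=psiBa), pA, rA, pB(G), (rBA=rBa(G))",8,488.29,7.62,0.01,472.29
WS,12,"psiA, psiBA, psiBa, pA, rA, pB(HD), (rBA=rBa(HD))",9,488.49,7.82,0.01,470.49
WS,13,"psiA, (psiBA=psiBa), pA, rA, pB, (rBA=rBa)",6,489.10,8.43,0.01,477.10
WS,14,"psiA, psiBA, psiBa, pA, rA, pB, (rBA=rBa)",7,489.51,8.84,0.00,475.51
WS,15,"psiA, psiBA, psiBa, pA, rA, pB(G), (rBA=rBa(G))",9,489.54,8.87,0.00,475.54
WS,16,"psiA, (psiBA=psiBa), pA, rA, pB, rBA, rBa",7,490.94,10.27,0.00,476.94
WS,17,"psiA, (psiBA=psiBa), pA(HD), rA(HD), pB(HD), rBA(HD), rBa(HD)",12,491.05,10.38,0.00,467.05
WS,18,"psiA, psiBA, psiBa, pA, rA, pB, rBA, rBa",8,491.31,10.64,0.00,475.31
WS,19,"psiA, psiBA, psiBa, pA(HD), rA(HD), pB(HD), rBA(HD), rBa(HD)",13,491.50,10.83,0.00,465.50
WS,20,"psiA, (psiBA=psiBa), pA(G+HD), rA(G+HD), pB(G+HD), rBA(G+HD), rBa(G+HD)",17,492.62,11.95,0.00,458.62
WS,21,"psiA, (psiBA=psiBa), pA(G), rA(G), pB(G), rBA(G), rBa(G)",12,492.73,12.06,0.00,468.73
WS,22,"psiA, psiBA, psiBa, pA(G), rA(G), pB(G), (rBA=rBa(G))",12,492.75,12.08,0.00,468.75
WS,23,"psiA, psiBA, psiBa, pA(G+HD), rA(G+HD), pB(G+HD), rBA(G+HD), rBa(G+HD)",18,493.20,12.53,0.00,457.20
WS,24,"psiA, (psiBA=psiBa), pA, rA, pB(HD), (rBA=rBa(HD))",8,494.57,13.90,0.00,478.57
WS,25,"psiA, psiBA, psiBa, pA(G), rA(G), pB(G), rBA(G), rBa(G)",13,495.72,15.05,0.00,469.72
FR,1,"psiA, (psiBA=psiBa), pA(E), rA(E), (pB=rBA=rBa(G+HD+E))",10,508.60,0.00,0.46,488.60
FR,2,"psiA, psiBA, psiBa, pA(E), rA(E), (pB=rBA=rBa(G+HD+E))",11,510.60,2.00,0.17,488.60
FR,3,"psiA, (psiBA=psiBa), pA(E), rA(E), (pB=rBA=rBa(HD+E))",9,511.28,2.68,0.12,493.28
FR,4,"psiA, psiBA, psiBa, pA(E), rA(E), (pB=rBA=rBa(HD+E))",10,513.20,4.60,0.05,493.20
FR,5,"psiA, (psiBA=psiBa), pA(E), rA(E), (pB=rBA=rBa(E))",8,513.38,4.78,0.04,497.38
FR,6,"psiA, (psiBA=psiBa), pA(E), rA(E), (pB=rBA=rBa(G+E))",9,514.00,5.40,0.03,496.00
FR,7,"psiA, (psiBA=psiBa), pA(G+HD+E), rA(G+HD+E), pB(G+HD+E), rBA(G+HD+E), rBa(G+HD+E)",22,514.47,5.87,0.02,470.47
FR,8,"psiA, (psiBA=psiBa), pA(E), rA(E), pB(HD+E), (rBA=rBa(HD+E))",12,514.95,6.35,0.02,490.95
FR,9,"psiA, psiBA, psiBa, pA(E), rA(E), (pB=rBA=rBa(E))",9,515.36,6.76,0.02,497.36
FR,10,"psiA, (psiBA=psiBa), pA(E), rA(E), pB(G+E), (rBA=rBa(G+E))",12,515.44,6.84,0.02,491.44
FR,11,"psiA, psiBA, psiBa, pA(E), rA(E), (pB=rBA=rBa(G+E))",10,516.00,7.40,0.01,496.00
FR,12,"psiA, (psiBA=psiBa), pA(E), rA(E), pB(E), (rBA=rBa(E))",10,516.25,7.65,0.01,496.25
FR,13,"psiA, psiBA, psiBa, pA(G+HD+E), rA(G+HD+E), pB(G+HD+E), rBA(G+HD+E), rBa(G+HD+E)",23,516.47,7.87,0.01,470.47
FR,14,"psiA, psiBA, psiBa, pA(E), rA(E), pB(HD+E), (rBA=rBa(HD+E))",13,516.95,8.35,0.01,490.95
FR,15,"psiA, psiBA, psiBa, pA(E), rA(E), pB(G+E), (rBA=rBa(G+E))",13,517.29,8.69,0.01,491.29
FR,16,"psiA, psiBA, psiBa, pA(E), rA(E), pB(E), (rBA=rBa(E))",11,518.24,9.64,0.00,496.24
FR,17,"psiA, (psiBA=psiBa), pA(HD+E), rA(HD+E), pB(HD+E), rBA(HD+E), rBa(HD+E)",17,518.72,10.12,0.00,484.72
FR,18,"psiA, (psiBA=psiBa), pA(E), rA(E), pB(E), rBA(E), rBa(E)",12,519.78,11.18,0.00,495.78
FR,19,"psiA, psiBA, psiBa, pA(G+E), rA(G+E), pB(G+E), (rBA=rBa(G+E))",15,520.51,11.91,0.00,490.51
FR,20,"psiA, psiBA, psiBa, pA(HD+E), rA(HD+E), pB(HD+E), rBA(HD+E), rBa(HD+E)",18,520.70,12.10,0.00,484.70
FR,21,"psiA, psiBA, psiBa, pA(E), rA(E), pB(E), rBA(E), rBa(E)",13,521.85,13.25,0.00,495.85
FR,22,"psiA, (psiBA=psiBa), pA(G+E), rA(G+E), pB(G+E), rBA(G+E), rBa(G+E)",17,522.25,13.65,0.00,488.25
FR,23,"psiA, psiBA, psiBa, pA(G+E), rA(G+E), pB(G+E), rBA(G+E), rBa(G+E)",18,525.03,16.43,0.00,489.03
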