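gene,class,dataset,probe_id,logFC,adj_p,present
KRT1,squamous,GSE13083,205900_at,-7.49126,1.11e-05,TRUE
KRT1,squamous,GSE34619,7963491,-3.3024845,1.10e-03,TRUE
KRT1,squamous,GSE1420,205900_at,-2.217323,0.277797,TRUE
KRT4,squamous,GSE13083,213240_s_at,-4.6401743,5.80e-02,TRUE
KRT4,squamous,GSE34619,7963534,-5.428193,2.16e-05,TRUE
KRT4,squamous,GSE1420,214399_s_at,0.9627934,0.291337,TRUE
KRT5,squamous,GSE13083,201820_at,-6.9473657,1.02e-02,TRUE
KRT5,squamous,GSE34619,7963427,-5.19733,1.27e-05,TRUE
KRT5,squamous,GSE1420,201820_at,0.2659335,0.939807,TRUE
KRT6,squamous,GSE13083,214580_x_at,-5.0172743,3.66e-02,TRUE
KRT6,squamous,GSE34619,7963410,-4.5273685,7.31e-05,TRUE
KRT6,squamous,GSE1420,214580_x_at,0.3930203,0.885997,TRUE
KRT10,squamous,GSE13083,207023_x_at,-1.9265443,4.80e-03,TRUE
KRT10,squamous,GSE34619,8015104,-1.9039765,1.43e-02,TRUE
KRT10,squamous,GSE1420,207023_x_at,0.0731168,0.925068,TRUE
KRT13,squamous,GSE13083,207935_s_at,-5.3344986,4.04e-02,TRUE
KRT13,squamous,GSE34619,8015323,-5.5419725,5.55e-05,TRUE
KRT13,squamous,GSE1420,207935_s_at,0.4701058,0.861817,TRUE
KRT14,squamous,GSE13083,209351_at,-4.0982471,1.17e-01,TRUE
KRT14,squamous,GSE34619,8015366,-2.2296553,1.88e-03,TRUE
KRT14,squamous,GSE1420,209351_at,1.928972,0.499067,TRUE
KRT15,squamous,GSE13083,204734_at,-6.05938,2.09e-03,TRUE
KRT15,squamous,GSE34619,8015337,-4.686177,2.79e-10,TRUE
KRT15,squamous,GSE1420,204734_at,-0.327417,0.941066,TRUE
KRT16,squamous,GSE13083,209800_at,-5.0731586,5.63e-03,TRUE
KRT16,squamous,GSE34619,8015376,-3.5205307,2.61e-05,TRUE
KRT16,squamous,GSE1420,209800_at,1.16582,0.682918,TRUE
KRT17,squamous,GSE13083,212236_x_at,-2.6745814,8.21e-02,TRUE
KRT17,squamous,GSE34619,8005449,-1.7824035,1.42e-03,TRUE
KRT17,squamous,GSE1420,205157_s_at,2.6061311,0.297826,TRUE
KRT23,squamous,GSE13083,218963_s_at,-2.0889186,3.74e-02,TRUE
KRT23,squamous,GSE34619,8015133,-1.2800192,7.70e-02,TRUE
KRT23,squamous,GSE1420,218963_s_at,0.0060589,0.997257,TRUE
KRT24,squamous,GSE13083,220267_at,-4.4806771,2.26e-03,TRUE
KRT24,squamous,GSE34619,8015060,-2.905637,7.73e-05,TRUE
KRT24,squamous,GSE1420,220267_at,-0.676433,0.81305,TRUE
KRT7,columnar,GSE13083,209016_s_at,2.2155471,4.07e-02,TRUE
KRT7,columnar,GSE34619,7955613,1.9065172,5.46e-06,TRUE
KRT7,columnar,GSE1420,209016_s_at,1.6998427,0.204673,TRUE
KRT8,columnar,GSE13083,209008_x_at,6.4172871,2.18e-09,TRUE
KRT8,columnar,GSE34619,7963567,4.0091988,3.50e-11,TRUE
KRT8,columnar,GSE1420,209008_x_at,2.6806701,0.027973,TRUE
KRT18,columnar,GSE13083,201596_x_at,3.4490243,5.03e-06,TRUE
KRT18,columnar,GSE34619,8154725,2.024285,2.16e-06,TRUE
KRT18,columnar,GSE1420,201596_x_at,1.9282774,0.082523,TRUE
KRT19,columnar,GSE13083,201650_at,1.7536714,1.01e-03,TRUE
KRT19,columnar,GSE34619,8015349,0.759105,3.08e-02,TRUE
KRT19,columnar,GSE1420,201650_at,1.2141959,0.658343,TRUE
KRT20,columnar,GSE13083,213953_at,8.5259443,3.44e-09,TRUE
KRT20,columnar,GSE34619,8015124,4.374532,2.00e-04,TRUE
KRT20,columnar,GSE1420,213953_at,4.8072071,0.037302,TRUE
TFF1,columnar,GSE13083,205009_at,8.2017486,1.75e-05,TRUE
TFF1,columnar,GSE34619,8070579,6.4595337,1.46e-12,TRUE
TFF1,columnar,GSE1420,205009_at,5.6843253,0.010407,TRUE
TFF2,columnar,GSE13083,214476_at,7.6665729,4.86e-05,TRUE
TFF2,columnar,GSE34619,8070574,5.2354248,1.23e-08,TRUE
TFF2,columnar,GSE1420,214476_at,5.8714482,0.006909,TRUE
TFF3,columnar,GSE13083,204623_at,8.9897857,9.11e-08,TRUE
TFF3,columnar,GSE34619,8070567,2.2346355,2.20e-04,TRUE
TFF3,columnar,GSE1420,204623_at,3.3738183,0.110978,TRUE
VIL1,columnar,GSE13083,209950_s_at,5.8340643,8.63e-09,TRUE
VIL1,columnar,GSE34619,8078665,2.2711873,1.88e-08,TRUE
VIL1,columnar,GSE1420,209950_s_at,2.5215122,0.025483,TRUE
MUC1,columnar,GSE13083,213693_s_at,1.5493643,1.21e-01,TRUE
MUC1,columnar,GSE34619,7920642,1.9449625,1.69e-05,TRUE
MUC1,columnar,GSE1420,213693_s_at,1.1435938,0.427828,TRUE
MUC2,columnar,GSE13083,204673_at,6.7226214,3.16e-06,TRUE
MUC2,columnar,GSE34619,7937560,2.1981597,2.77e-03,TRUE
MUC2,columnar,GSE1420,204673_at,2.9508572,0.271622,TRUE
MUC3A/B,columnar,GSE13083,217117_x_at,0.7757457,9.80e-02,TRUE
MUC3A/B,columnar,GSE34619,8135015,4.3127432,6.68e-09,TRUE
MUC3A/B,columnar,GSE1420,217117_x_at,0.9212935,0.225325,TRUE
MUC4,columnar,GSE13083,217109_at,-1.07354,1.13e-01,TRUE
MUC4,columnar,GSE34619,8092978,0.1271057,8.92e-01,TRUE
MUC4,columnar,GSE1420,204895_x_at,1.903752,0.360547,TRUE
MUC5ac,columnar,GSE13083,214385_s_at,8.1766871,8.25e-07,TRUE
MUC5ac,columnar,GSE34619,,,,FALSE
MUC5ac,columnar,GSE1420,214385_s_at,7.1466461,0.005318,TRUE
MUC5B,columnar,GSE13083,213432_at,2.7593857,4.75e-02,TRUE
MUC5B,columnar,GSE34619,7937612,1.6075105,2.00e-03,TRUE
MUC5B,columnar,GSE1420,213432_at,2.3107749,0.510519,TRUE
MUC6,columnar,GSE13083,214133_at,3.1026371,7.45e-03,TRUE
MUC6,columnar,GSE34619,7945595,5.9384813,1.46e-11,TRUE
MUC6,columnar,GSE1420,214133_at,3.4098322,0.017934,TRUE
MUC12,columnar,GSE13083,,,,FALSE
MUC12,columnar,GSE34619,8135033,2.2172345,1.33e-03,TRUE
MUC12,columnar,GSE1420,,,,FALSE
MUC13,columnar,GSE13083,218687_s_at,7.3541829,5.65e-10,TRUE
MUC13,columnar,GSE34619,8090180,7.3474513,1.87e-11,TRUE
MUC13,columnar,GSE1420,218687_s_at,3.6273263,0.031468,TRUE
MUC15,columnar,GSE13083,,,,FALSE
MUC15,columnar,GSE34619,7947156,-4.7653307,4.28e-10,TRUE
MUC15,columnar,GSE1420,,,,FALSE
MUC17,columnar,GSE13083,,,,FALSE
MUC17,columnar,GSE34619,8135048,5.953779,6.32e-08,TRUE
MUC17,columnar,GSE1420,,,,FALSE
MUC21,columnar,GSE13083,,,,FALSE
MUC21,columnar,GSE34619,8177931,-5.732196,5.46e-07,TRUE
MUC21,columnar,GSE1420,,,,FALSE
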