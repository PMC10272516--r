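{
 "description": "Magnetic field of unit current dipoles in a spherical conductor (radius-independent Sarvas field, sphere centre at origin), computed with an independent reference implementation (MNE-Python 1.13 sphere-model kernel). Rows of B: source-major, moment components x,y,z; columns: field component along sensor orientation at sensor position, tesla per A*m.",
 "sensors_pos": [
  [
   0.023840319695407345,
   0.0,
   0.11760798934094899
  ],
  [
   0.015389492398720341,
   0.05543452824241515,
   0.10530990742684472
  ],
  [
   -0.08054688228852531,
   0.04845673157971629,
   0.07459319619247973
  ],
  [
   -0.06990384069250288,
   -0.08093615447175427,
   0.05443153457106928
  ],
  [
   0.029219993668545496,
   -0.07157114321518432,
   0.09178106247413861
  ],
  [
   0.03574122920400575,
   0.030104422062001715,
   0.1105273192803462
  ]
 ],
 "sensors_ori": [
  [
   0.003033931306655539,
   0.736797110260639,
   -0.676107102146101
  ],
  [
   -0.6323984977372045,
   -0.32285622772920797,
   -0.7041562300201516
  ],
  [
   0.042087685075105526,
   0.9378646231969613,
   -0.3444395089426308
  ],
  [
   -0.7153653745955425,
   0.5647545804432578,
   0.4114664563462483
  ],
  [
   0.11251663010909582,
   -0.9931591773409472,
   -0.031222690664738276
  ],
  [
   0.4397684526343243,
   -0.8501947872232488,
   -0.289434849052471
  ]
 ],
 "sources": [
  [
   0.02,
   0.01,
   0.05
  ],
  [
   0.0,
   0.0,
   0.03
  ],
  [
   -0.03,
   0.04,
   0.02
  ],
  [
   0.01,
   -0.05,
   0.06
  ]
 ],
 "B": [
  [
   -9.603319195578724e-07,
   -3.1544485089581578e-06,
   -1.5097267904603039e-06,
   -1.1072549949751994e-06,
   -3.1197037206963825e-06,
   3.2313858982969214e-06
  ],
  [
   -1.6889140160974669e-06,
   -4.486624219827634e-06,
   1.3462580937120407e-06,
   -7.142404839501481e-07,
   7.956999978852655e-07,
   2.051263185356099e-06
  ],
  [
   7.219155710426421e-07,
   2.1591042475487893e-06,
   3.346390974417133e-07,
   5.857500947801094e-07,
   1.0887414887015e-06,
   -1.7028069963899884e-06
  ],
  [
   -1.1184428948907887e-06,
   -1.4973915685188167e-06,
   -7.549140055526153e-07,
   -9.644908609194322e-07,
   -5.425194713339449e-07,
   7.696889056241731e-07
  ],
  [
   7.246859882986811e-07,
   -3.4410713767627435e-07,
   6.182373736568922e-07,
   -4.358261938592789e-07,
   -5.990564818221549e-07,
   1.1842033988126272e-06
  ],
  [
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0
  ],
  [
   1.6018090339978822e-06,
   2.9121076745423337e-06,
   -2.058150874216278e-06,
   2.4641699740364865e-07,
   -1.3255267641755706e-06,
   3.7449978687951575e-07
  ],
  [
   1.8441085333214441e-06,
   2.816352498577191e-06,
   -5.922829209166686e-07,
   -4.1896204013614664e-08,
   -1.088686016016831e-06,
   1.9948032091619166e-07
  ],
  [
   -1.2855035156460659e-06,
   -1.26454348534088e-06,
   -1.9026604694910797e-06,
   4.5341790413270223e-07,
   1.8908188577030585e-07,
   1.6278903848689015e-07
  ],
  [
   -4.809332941451566e-06,
   -3.918513040103657e-06,
   8.930294600789498e-07,
   -5.232133042535423e-06,
   1.602815973897786e-05,
   -3.5493898734308237e-06
  ],
  [
   7.184604580785687e-07,
   -1.187022167752692e-06,
   1.7346123836152051e-06,
   8.035849923001146e-07,
   -4.158375684510606e-06,
   2.4016913759710656e-06
  ],
  [
   1.4002725386407348e-06,
   -3.360996331099676e-07,
   1.2966720763328462e-06,
   1.5416763340059997e-06,
   -6.136673026921816e-06,
   2.5929744588810255e-06
  ]
 ]
}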