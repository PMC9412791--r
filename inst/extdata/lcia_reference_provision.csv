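category_id,baseline,bamboo,paper_bag,bamboo_paper_bag,exclude_water
CC,2.89E+00,2.72E+00,2.87E+00,2.71E+00,1.85E+00
EAC,1.36E-02,1.32E-02,1.36E-02,1.31E-02,8.33E-03
ECF,5.28E+00,5.21E+00,5.29E+00,5.21E+00,2.28E+00
EUF,1.06E-03,9.60E-04,1.07E-03,9.60E-04,5.40E-04
EUM,3.70E-03,3.72E-03,3.71E-03,3.73E-03,2.50E-03
EUT,2.80E-02,2.79E-02,2.81E-02,2.80E-02,1.64E-02
HCE,2.59E-07,2.56E-07,2.59E-07,2.56E-07,4.38E-08
HIR,2.40E-01,2.19E-01,2.40E-01,2.20E-01,6.19E-02
HNC,4.51E-07,4.53E-07,4.52E-07,4.53E-07,1.50E-07
HRI,2.28E-07,2.31E-07,2.28E-07,2.31E-07,1.44E-07
HOF,9.24E-03,9.02E-03,9.24E-03,9.02E-03,5.61E-03
RLU,2.08E+01,2.77E+01,2.42E+01,3.12E+01,1.21E+01
HOD,3.33E-07,1.34E-07,3.33E-07,1.35E-07,2.67E-07
RFF,5.19E+01,4.69E+01,5.16E+01,4.65E+01,3.57E+01
RMM,1.87E-05,1.65E-05,1.87E-05,1.64E-05,9.46E-06
RDW,8.37E+00,8.29E+00,8.37E+00,8.28E+00,1.58E+00
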