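category_id,baseline,bamboo,double_paste
CC,1.95E+00,1.66E+00,2.08E+00
EAC,8.11E-03,7.18E-03,8.75E-03
ECF,3.22E+00,2.86E+00,3.25E+00
EUF,5.30E-04,3.80E-04,5.80E-04
EUM,1.93E-03,1.88E-03,2.17E-03
EUT,1.75E-02,1.64E-02,1.85E-02
HCE,1.04E-07,9.53E-08,1.04E-07
HIR,1.41E-01,1.09E-01,1.40E-01
HNC,1.96E-07,1.89E-07,2.06E-07
HRI,9.02E-08,8.97E-08,1.08E-07
HOF,5.97E-03,5.37E-03,6.32E-03
RLU,1.17E+01,1.96E+01,1.25E+01
HOD,3.92E-07,1.27E-07,3.82E-07
RFF,3.19E+01,2.44E+01,3.50E+01
RMM,1.79E-05,1.38E-05,1.70E-05
RDW,2.43E+00,2.32E+00,2.66E+00
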