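category,supervised,provision
global_warming,1.81359E-06,2.6799E-06
stratospheric_ozone_depletion,2.0815E-10,1.7668E-10
ionising_radiation,1.19944E-09,2.0407E-09
particulate_matter_formation,5.67928E-11,1.4382E-10
photochemical_ozone_formation,5.23136E-09,8.0968E-09
cancer_effects,3.44848E-13,8.5907E-13
non_cancer_effects,1.30085E-15,3.0017E-15
water_consumption,1.78949E-06,6.1534E-06
total,3.60978E-06,8.8438E-06
daly_seconds,113.8380508,278.898726
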