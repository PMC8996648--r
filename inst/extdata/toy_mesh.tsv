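Cohort Studies	E05.318.760
Depression	F03.600.300
Disease-Free Survival	E01.789.200
Disease-Free Survival	E05.318.740.600.200
Follow-Up Studies	E05.318.760.500.400
Hospital Mortality	E05.318.308.985.550.300
Incidence	E05.318.308.985.525
Longitudinal Studies	E05.318.760.500
Lung Neoplasms	C04.588.894
Mortality	E05.318.308.985.550
Neoplasms	C04
Prevalence	E05.318.308.985.525.750
Prognosis	E01.789
Prospective Studies	E05.318.760.500.750
Retrospective Studies	E05.318.760.600
Risk	N06.850
Risk Assessment	N06.850.520
Risk Factors	N06.850.505
Survival Analysis	E05.318.740.600
Survival Rate	E05.318.740.600.800
Wound Healing	G16.100.856
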