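ligand,receptor,ka,ka_se
IgG1,FcgRI,6.5e7,6.5e6
IgG1,FcgRIIA-131H,5.2e6,5.2e5
IgG1,FcgRIIA-131R,3.5e6,3.5e5
IgG1,FcgRIIB-232I,1.2e5,1.2e4
IgG1,FcgRIIIA-158F,1.2e6,1.2e5
IgG1,FcgRIIIA-158V,2.0e6,2.0e5
IgG2,FcgRI,0,0
IgG2,FcgRIIA-131H,4.5e5,4.5e4
IgG2,FcgRIIA-131R,1.0e5,1.0e4
IgG2,FcgRIIB-232I,2.0e4,2.0e3
IgG2,FcgRIIIA-158F,3.0e4,3.0e3
IgG2,FcgRIIIA-158V,7.0e4,7.0e3
IgG3,FcgRI,6.1e7,6.1e6
IgG3,FcgRIIA-131H,8.9e5,8.9e4
IgG3,FcgRIIA-131R,9.1e5,9.1e4
IgG3,FcgRIIB-232I,1.7e5,1.7e4
IgG3,FcgRIIIA-158F,7.7e6,7.7e5
IgG3,FcgRIIIA-158V,9.8e6,9.8e5
IgG4,FcgRI,3.4e7,3.4e6
IgG4,FcgRIIA-131H,1.7e5,1.7e4
IgG4,FcgRIIA-131R,2.1e5,2.1e4
IgG4,FcgRIIB-232I,2.0e5,2.0e4
IgG4,FcgRIIIA-158F,2.0e5,2.0e4
IgG4,FcgRIIIA-158V,2.5e5,2.5e4
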