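cell,receptor,rtot
cMO,FcgRI,3.0e4
cMO,FcgRIIA-131H,8.0e4
cMO,FcgRIIB-232I,8.0e3
cMO,FcgRIIIA-158V,3.0e3
ncMO,FcgRI,6.0e3
ncMO,FcgRIIA-131H,5.0e4
ncMO,FcgRIIB-232I,2.0e4
ncMO,FcgRIIIA-158V,1.2e5
Neu,FcgRI,2.0e3
Neu,FcgRIIA-131H,1.5e5
Neu,FcgRIIB-232I,5.0e3
Neu,FcgRIIIA-158V,2.0e3
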