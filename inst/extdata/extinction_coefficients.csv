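"wavelength_nm","hbo","hb"
760,0.5864,1.5485
830,0.974,0.693
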