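(((I_scapularis,R_microplus),I_ricinus),(G_occidentalis,((V_destructor,V_jacobsoni),T_mercedesae)));
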