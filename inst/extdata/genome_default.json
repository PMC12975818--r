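{"tau_u":1,"tau_v":104.932355990967,"i_ext":2.21951804410877,"dur_pre":751.997480600683,"dur_post":796.262223732201,"w_plus":2.10572861778438,"u_gain":1.77927329189113,"u_offset":1.04506125503735,"u_threshold":0.275505030965336,"v_gain":20.9730573467196,"v_offset":-0.12518848903466,"v_threshold":0.261090608903128,"phi_v_alpha":0.352577649911687,"phi_v_slope":0.1,"phi_v_offset":0.918244614756166,"phi_v_center":0.194133610473819,"phi_v_width":0.14209612756122,"phi_eta_alpha":0.948305744367407,"phi_eta_slope":7.3891448280298,"phi_eta_offset":1.4590599725361,"phi_eta_center":0.252529667337845,"phi_eta_width":0.283126116875756,"schema_version":1}
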