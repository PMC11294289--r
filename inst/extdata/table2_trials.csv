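speaker_id,session,response_form,condition,emitted
child_t2,1,iPad,Tact,0
child_t2,1,iPad,Mand,0
child_t2,1,iPad,Echoic,1
child_t2,1,iPad,Sequelic,0
child_t2,1,Guitar,Tact,1
child_t2,1,Guitar,Mand,0
child_t2,1,Guitar,Echoic,1
child_t2,1,Guitar,Sequelic,0
child_t2,1,Spider,Tact,1
child_t2,1,Spider,Mand,0
child_t2,1,Spider,Echoic,1
child_t2,1,Spider,Sequelic,1
child_t2,1,Lion,Tact,1
child_t2,1,Lion,Mand,1
child_t2,1,Lion,Echoic,1
child_t2,1,Lion,Sequelic,0
child_t2,1,Phone,Tact,1
child_t2,1,Phone,Mand,0
child_t2,1,Phone,Echoic,0
child_t2,1,Phone,Sequelic,0
child_t2,1,Step on it,Tact,1
child_t2,1,Step on it,Mand,1
child_t2,1,Step on it,Echoic,1
child_t2,1,Step on it,Sequelic,0
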