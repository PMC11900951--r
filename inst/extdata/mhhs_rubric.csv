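item_id,domain,retained,code,points
pain,pain,TRUE,0,44
pain,pain,TRUE,1,40
pain,pain,TRUE,2,30
pain,pain,TRUE,3,20
pain,pain,TRUE,4,10
pain,pain,TRUE,5,0
limp,gait,TRUE,0,11
limp,gait,TRUE,1,8
limp,gait,TRUE,2,5
limp,gait,TRUE,3,0
support,gait,TRUE,0,11
support,gait,TRUE,1,7
support,gait,TRUE,2,5
support,gait,TRUE,3,3
support,gait,TRUE,4,2
support,gait,TRUE,5,0
walk_distance,gait,TRUE,0,11
walk_distance,gait,TRUE,1,8
walk_distance,gait,TRUE,2,5
walk_distance,gait,TRUE,3,2
walk_distance,gait,TRUE,4,0
stairs,activities,TRUE,0,4
stairs,activities,TRUE,1,2
stairs,activities,TRUE,2,1
stairs,activities,TRUE,3,0
shoes_socks,activities,TRUE,0,4
shoes_socks,activities,TRUE,1,2
shoes_socks,activities,TRUE,2,0
sitting,activities,TRUE,0,5
sitting,activities,TRUE,1,3
sitting,activities,TRUE,2,0
public_transport,activities,FALSE,0,1
public_transport,activities,FALSE,1,0
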