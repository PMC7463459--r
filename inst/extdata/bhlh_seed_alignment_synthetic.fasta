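>seed01 synthetic bHLH domain seed row
ADRRKAANHRERERRRRINISERLRELQELVPNGTKASMDKASMLDEAIEYVKFL
>seed02 synthetic bHLH domain seed row
ADRRKAANHRERERRRRINISERLRELQELVPNGTKASMDKASMLDEAIEYVKFL
>seed03 synthetic bHLH domain seed row
ADRRKAANHRERERRRRINISERLRELQELVPNGTKASMDKASMLDEAIEYVKFL
>seed04 synthetic bHLH domain seed row
ADRRKAANHRERERRRRINISERLRELQELVPNGTKASMDKASMLDEAIEYVKFL
>seed05 synthetic bHLH domain seed row
ADRRKAANHRERERRRRINISERLRELQELVPNGTKASMDKASMLDEAIEYVKFL
>seed06 synthetic bHLH domain seed row
ADRRKAANHRERERRRRINISERLRELQELVPNGTKASMDKASMLDEAIEYVKFL
>seed07 synthetic bHLH domain seed row
AERRKSANHRERERRRRIRIAERLRELQELVPSGSKASMDKAAMLDEAIDYVKFL
>seed08 synthetic bHLH domain seed row
SDRRKAAQHRERERRRRINISERLKELQDLVPNNTKPSMDKASMLEEAIEYVKYL
>seed09 synthetic bHLH domain seed row
ADRKKAANHKERERRRRINISDRLRELQELIPNGTRASLDKASMLDQAIEFVKFL
>seed10 synthetic bHLH domain seed row
ADKRKAANHREQERRRRINVSERLRELQEMVPNGTKATMDRASMMDEAIEYVRFL
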