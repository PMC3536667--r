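item,lower,upper,value
sitting_h_per_day,0,0.5,0.25
sitting_h_per_day,0.5,1,0.75
sitting_h_per_day,1,2,1.5
sitting_h_per_day,2,3,2.5
sitting_h_per_day,3,4,3.5
sitting_h_per_day,4,5,4.5
sitting_h_per_day,5,6,5.5
sitting_h_per_day,6,7,6.5
sitting_h_per_day,7,8,7.5
sitting_h_per_day,8,9,8.5
sitting_h_per_day,9,10,9.5
sitting_h_per_day,10,Inf,10
activity_h_per_day,0,0.25,0.125
activity_h_per_day,0.25,0.5,0.375
activity_h_per_day,0.5,0.75,0.625
activity_h_per_day,0.75,1,0.875
activity_h_per_day,1,1.5,1.25
activity_h_per_day,1.5,2,1.75
activity_h_per_day,2,Inf,2
job_h_per_week,0,5,2.5
job_h_per_week,5,10,7.5
job_h_per_week,10,15,12.5
job_h_per_week,15,20,17.5
job_h_per_week,20,25,22.5
job_h_per_week,25,30,27.5
job_h_per_week,30,35,32.5
job_h_per_week,35,40,37.5
job_h_per_week,40,45,42.5
job_h_per_week,45,50,47.5
job_h_per_week,50,55,52.5
job_h_per_week,55,60,57.5
job_h_per_week,60,Inf,60
screen_h_per_day,0,0.5,0.25
screen_h_per_day,0.5,1,0.75
screen_h_per_day,1,2,1.5
screen_h_per_day,2,3,2.5
screen_h_per_day,3,4,3.5
screen_h_per_day,4,5,4.5
screen_h_per_day,5,6,5.5
screen_h_per_day,6,Inf,6
household_h_per_week,0,1,0.5
household_h_per_week,1,2,1.5
household_h_per_week,2,3,2.5
household_h_per_week,3,4,3.5
household_h_per_week,4,5,4.5
household_h_per_week,5,6,5.5
household_h_per_week,6,7,6.5
household_h_per_week,7,8,7.5
household_h_per_week,8,9,8.5
household_h_per_week,9,10,9.5
household_h_per_week,10,11,10.5
household_h_per_week,11,12,11.5
household_h_per_week,12,13,12.5
household_h_per_week,13,14,13.5
household_h_per_week,14,Inf,14
sleeping_h_per_night,0,5,4.5
sleeping_h_per_night,5,6,5.5
sleeping_h_per_night,6,7,6.5
sleeping_h_per_night,7,8,7.5
sleeping_h_per_night,8,9,8.5
sleeping_h_per_night,9,10,9.5
sleeping_h_per_night,10,11,10.5
sleeping_h_per_night,11,12,11.5
sleeping_h_per_night,12,Inf,12
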