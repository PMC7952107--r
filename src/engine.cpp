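// Event-driven simulation core for the low-acuity ED pathway.
//
// All randomness is drawn in R beforehand (arrival times, ESI labels,
// testing/resident assignments, per-patient service durations), so this
// executor is fully deterministic: it resolves resource contention
// (rooms, nurses, providers, residents) with FIFO queues and returns the
// per-patient milestone timestamps.
//
// Pathway: arrival -> nurse (screening + vitals) -> wait for room ->
// transfer to room -> wait for provider -> evaluation (attending, or
// resident evaluation + attending/resident review) -> [if tested:
// testing & treatment delay, then provider reassessment] -> nurse
// discharge -> disposition -> bed cleaning -> room released.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

enum Phase {
  ARRIVE,
  TRIAGE_DONE,     // screening + vitals finished, release nurse
  TRANSFER_DONE,   // patient in room
  RES_EVAL_DONE,   // resident evaluation finished
  EVAL_DONE,       // attending eval or attending/resident review finished
  TEST_DONE,       // testing & treatment delay elapsed
  REASSESS_DONE,   // provider reassessment finished
  DISCHARGE_DONE,  // disposition; schedule cleaning
  CLEAN_DONE       // room released
};

struct Event {
  double time;
  std::int64_t seq;
  int pid;
  int phase;
};

struct EventOrder {
  bool operator()(const Event& a, const Event& b) const {
    if (a.time != b.time) return a.time > b.time;
    return a.seq > b.seq;  // FIFO tie-break on simultaneous events
  }
};

// Queued request for a staff resource: which patient, which task.
enum Task { T_TRIAGE, T_DISCHARGE, T_EVAL, T_REVIEW, T_REASSESS, T_RESEVAL };

struct Request {
  int pid;
  int task;
};

struct Engine {
  // inputs
  const NumericVector& arrival;
  const IntegerVector& esi;
  const LogicalVector& tested;
  const LogicalVector& resident_path;
  const NumericMatrix& dur;  // columns: see col enum below
  long rooms_free, nurses_free, providers_free, residents_free;

  enum Col { D_SCREEN, D_VITALS, D_TRANSFER, D_ATT_EVAL, D_RES_EVAL,
             D_REVIEW, D_REASSESS, D_TESTING, D_DISCHARGE, D_CLEANING };

  std::priority_queue<Event, std::vector<Event>, EventOrder> events;
  std::deque<int> room_queue;
  std::deque<Request> nurse_queue, provider_queue, resident_queue;
  std::int64_t seq = 0;

  // outputs (absolute minutes since simulation start)
  std::vector<double> screening_start, screening_end, vitals_end,
      room_acquired, room_entry, provider_start, disposition,
      discharge_start, cleaning_end, nurse_min, provider_min;

  Engine(const NumericVector& arrival_, const IntegerVector& esi_,
         const LogicalVector& tested_, const LogicalVector& resident_,
         const NumericMatrix& dur_, long rooms, long nurses,
         long providers, long residents)
      : arrival(arrival_), esi(esi_), tested(tested_),
        resident_path(resident_), dur(dur_), rooms_free(rooms),
        nurses_free(nurses), providers_free(providers),
        residents_free(residents) {
    size_t n = arrival.size();
    screening_start.assign(n, NA_REAL);
    screening_end.assign(n, NA_REAL);
    vitals_end.assign(n, NA_REAL);
    room_acquired.assign(n, NA_REAL);
    room_entry.assign(n, NA_REAL);
    provider_start.assign(n, NA_REAL);
    disposition.assign(n, NA_REAL);
    discharge_start.assign(n, NA_REAL);
    cleaning_end.assign(n, NA_REAL);
    nurse_min.assign(n, 0.0);
    provider_min.assign(n, 0.0);
  }

  void schedule(double t, int pid, int phase) {
    events.push(Event{t, seq++, pid, phase});
  }

  void start_triage(int pid, double t) {
    screening_start[pid] = t;
    screening_end[pid] = t + dur(pid, D_SCREEN);
    vitals_end[pid] = screening_end[pid] + dur(pid, D_VITALS);
    nurse_min[pid] += dur(pid, D_SCREEN) + dur(pid, D_VITALS);
    schedule(vitals_end[pid], pid, TRIAGE_DONE);
  }

  void start_discharge(int pid, double t) {
    discharge_start[pid] = t;
    nurse_min[pid] += dur(pid, D_DISCHARGE);
    schedule(t + dur(pid, D_DISCHARGE), pid, DISCHARGE_DONE);
  }

  void start_eval(int pid, double t) {
    provider_start[pid] = t;
    provider_min[pid] += dur(pid, D_ATT_EVAL);
    schedule(t + dur(pid, D_ATT_EVAL), pid, EVAL_DONE);
  }

  void start_res_eval(int pid, double t) {
    provider_start[pid] = t;
    schedule(t + dur(pid, D_RES_EVAL), pid, RES_EVAL_DONE);
  }

  void start_review(int pid, double t) {
    provider_min[pid] += dur(pid, D_REVIEW);
    schedule(t + dur(pid, D_REVIEW), pid, EVAL_DONE);
  }

  void start_reassess(int pid, double t) {
    provider_min[pid] += dur(pid, D_REASSESS);
    schedule(t + dur(pid, D_REASSESS), pid, REASSESS_DONE);
  }

  void dispatch_nurse(const Request& r, double t) {
    if (r.task == T_TRIAGE) start_triage(r.pid, t);
    else start_discharge(r.pid, t);
  }

  void dispatch_provider(const Request& r, double t) {
    if (r.task == T_EVAL) start_eval(r.pid, t);
    else if (r.task == T_REVIEW) start_review(r.pid, t);
    else start_reassess(r.pid, t);
  }

  void request_nurse(int pid, int task, double t) {
    if (nurses_free > 0) {
      --nurses_free;
      dispatch_nurse(Request{pid, task}, t);
    } else {
      nurse_queue.push_back(Request{pid, task});
    }
  }

  void release_nurse(double t) {
    if (!nurse_queue.empty()) {
      Request r = nurse_queue.front();
      nurse_queue.pop_front();
      dispatch_nurse(r, t);
    } else {
      ++nurses_free;
    }
  }

  void request_provider(int pid, int task, double t) {
    if (providers_free > 0) {
      --providers_free;
      dispatch_provider(Request{pid, task}, t);
    } else {
      provider_queue.push_back(Request{pid, task});
    }
  }

  void release_provider(double t) {
    if (!provider_queue.empty()) {
      Request r = provider_queue.front();
      provider_queue.pop_front();
      dispatch_provider(r, t);
    } else {
      ++providers_free;
    }
  }

  void request_resident(int pid, double t) {
    if (residents_free > 0) {
      --residents_free;
      start_res_eval(pid, t);
    } else {
      resident_queue.push_back(Request{pid, T_RESEVAL});
    }
  }

  void release_resident(double t) {
    if (!resident_queue.empty()) {
      Request r = resident_queue.front();
      resident_queue.pop_front();
      start_res_eval(r.pid, t);
    } else {
      ++residents_free;
    }
  }

  void start_transfer(int pid, double t) {
    room_acquired[pid] = t;
    room_entry[pid] = t + dur(pid, D_TRANSFER);
    schedule(room_entry[pid], pid, TRANSFER_DONE);
  }

  void request_room(int pid, double t) {
    if (rooms_free > 0) {
      --rooms_free;
      start_transfer(pid, t);
    } else {
      room_queue.push_back(pid);
    }
  }

  void release_room(double t) {
    if (!room_queue.empty()) {
      int pid = room_queue.front();
      room_queue.pop_front();
      start_transfer(pid, t);
    } else {
      ++rooms_free;
    }
  }

  void run() {
    for (int i = 0; i < arrival.size(); ++i) {
      schedule(arrival[i], i, ARRIVE);
    }
    while (!events.empty()) {
      Event e = events.top();
      events.pop();
      const int pid = e.pid;
      const double t = e.time;
      switch (e.phase) {
        case ARRIVE:
          request_nurse(pid, T_TRIAGE, t);
          break;
        case TRIAGE_DONE:
          release_nurse(t);
          request_room(pid, t);
          break;
        case TRANSFER_DONE:
          if (resident_path[pid]) request_resident(pid, t);
          else request_provider(pid, T_EVAL, t);
          break;
        case RES_EVAL_DONE:
          release_resident(t);
          request_provider(pid, T_REVIEW, t);
          break;
        case EVAL_DONE:
          release_provider(t);
          if (tested[pid]) {
            schedule(t + dur(pid, D_TESTING), pid, TEST_DONE);
          } else {
            request_nurse(pid, T_DISCHARGE, t);
          }
          break;
        case TEST_DONE:
          request_provider(pid, T_REASSESS, t);
          break;
        case REASSESS_DONE:
          release_provider(t);
          request_nurse(pid, T_DISCHARGE, t);
          break;
        case DISCHARGE_DONE:
          release_nurse(t);
          disposition[pid] = t;
          cleaning_end[pid] = t + dur(pid, D_CLEANING);
          schedule(cleaning_end[pid], pid, CLEAN_DONE);
          break;
        case CLEAN_DONE:
          release_room(t);
          break;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_ed_cpp")]]
List sim_ed_cpp(NumericVector arrival, IntegerVector esi,
                LogicalVector tested, LogicalVector resident_path,
                NumericMatrix dur, double n_rooms, double n_nurses,
                double n_providers, double n_residents) {
  const int n = arrival.size();
  if (esi.size() != n || tested.size() != n || resident_path.size() != n ||
      dur.nrow() != n || dur.ncol() != 10) {
    stop("inconsistent input dimensions");
  }
  for (int i = 1; i < n; ++i) {
    if (arrival[i] < arrival[i - 1]) stop("arrival times must be sorted");
  }
  Engine eng(arrival, esi, tested, resident_path, dur,
             (long)n_rooms, (long)n_nurses, (long)n_providers,
             (long)n_residents);
  eng.run();
  return List::create(
      _["screening_start"] = wrap(eng.screening_start),
      _["screening_end"] = wrap(eng.screening_end),
      _["vitals_end"] = wrap(eng.vitals_end),
      _["room_acquired"] = wrap(eng.room_acquired),
      _["room_entry"] = wrap(eng.room_entry),
      _["provider_start"] = wrap(eng.provider_start),
      _["discharge_start"] = wrap(eng.discharge_start),
      _["disposition"] = wrap(eng.disposition),
      _["cleaning_end"] = wrap(eng.cleaning_end),
      _["nurse_min"] = wrap(eng.nurse_min),
      _["provider_min"] = wrap(eng.provider_min));
}
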